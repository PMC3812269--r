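#' Build a rigid C60 fullerene ball
#'
#' Constructs the 60 carbon sites of a C60 cage as the vertices of an ideal
#' equal-edge truncated icosahedron, uniformly scaled so that the circumradius
#' (atom-to-centre distance) equals `radius`, then rotated and translated.
#' Real C60 has two slightly different bond lengths; since every site carries
#' the same Lennard-Jones type here, the ideal equal-edge cage is used.
#'
#' @param radius circumradius of the cage in nm (default 0.35, the standard
#'   C60 van der Waals cage radius).
#' @param center 3-vector, nm; position of the cage centre.
#' @param rotation 3x3 rotation matrix applied to the cage before translation.
#' @param ball_id integer identifier carried through cluster analyses.
#' @return An object of class `fullerene_ball`: list with `ball_id`, `center`
#'   (3-vector, nm) and `atom_coords` (60 x 3 matrix, absolute nm).
#' @examples
#' ball <- build_c60()
#' range(sqrt(rowSums(sweep(ball$atom_coords, 2, ball$center)^2)))
#' @export
build_c60 <- function(radius = 0.35, center = c(0, 0, 0), rotation = diag(3),
                      ball_id = 1L) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stop("invalid-argument: `radius` must be a single finite positive number")
  }
  if (length(center) != 3L || !all(is.finite(center))) {
    stop("invalid-argument: `center` must be a finite 3-vector")
  }
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3L, 3L)))
  v <- .trunc_icosa_vertices() * radius
  v <- v %*% t(rotation)
  v <- sweep(v, 2L, center, "+")
  structure(
    list(ball_id = as.integer(ball_id), center = as.numeric(center),
         atom_coords = v),
    class = "fullerene_ball"
  )
}

# Unit-circumradius equal-edge truncated icosahedron: the 60 vertices are the
# cyclic permutations of (0, +-1, +-3*phi), (+-1, +-(2+phi), +-2*phi),
# (+-2, +-(1+2*phi), +-phi), circumradius sqrt(9*phi+10), edge length 2.
.trunc_icosa_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  base <- rbind(c(0, 1, 3 * phi),
                c(1, 2 + phi, 2 * phi),
                c(2, 1 + 2 * phi, phi))
  out <- matrix(0, 60L, 3L)
  n <- 0L
  for (k in 1:3) {
    for (i in 1:3) {
      p <- switch(k, base[i, ], base[i, c(2, 3, 1)], base[i, c(3, 1, 2)])
      for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1)) {
        w <- p * c(s1, s2, s3)
        # the zero coordinate makes half the sign combinations duplicates
        if (n > 0L && any(colSums(abs(t(out[seq_len(n), , drop = FALSE]) - w)) < 1e-9)) next
        n <- n + 1L
        out[n, ] <- w
      }
    }
  }
  stopifnot(n == 60L)
  out / sqrt(9 * phi + 10)
}

#' @export
print.fullerene_ball <- function(x, ...) {
  r <- mean(sqrt(rowSums(sweep(x$atom_coords, 2, x$center)^2)))
  cat(sprintf("<fullerene_ball id=%d> 60 atoms, radius %.4f nm, center (%.3f, %.3f, %.3f)\n",
              x$ball_id, r, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Uniform random rotation matrices
#'
#' Draws rotations uniformly over SO(3) via random unit quaternions
#' (Shoemake's method). Uses the current R random stream; call `set.seed()`
#' for reproducibility.
#'
#' @param n number of rotations.
#' @return A single 3x3 matrix if `n == 1`, otherwise a list of matrices.
#' @export
random_rotation <- function(n = 1L) {
  one <- function() {
    u <- runif(3)
    q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
           sqrt(1 - u[1]) * cos(2 * pi * u[2]),
           sqrt(u[1]) * sin(2 * pi * u[3]),
           sqrt(u[1]) * cos(2 * pi * u[3]))
    x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
             2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
             2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
           3L, 3L, byrow = TRUE)
  }
  if (n == 1L) one() else replicate(n, one(), simplify = FALSE)
}

#' Define a simulation box
#'
#' @param lengths 3-vector of box edge lengths, nm; all > 0.
#' @param periodic logical 3-vector: which of x, y, z are periodic. Membrane
#'   systems conventionally use xy-periodic, z-finite.
#' @return An object of class `simulation_box`.
#' @export
simulation_box <- function(lengths, periodic = c(TRUE, TRUE, TRUE)) {
  lengths <- as.numeric(lengths)
  if (length(lengths) != 3L || !all(is.finite(lengths)) || any(lengths <= 0)) {
    stop("invalid-argument: box lengths must be three finite positive numbers")
  }
  stopifnot(is.logical(periodic), length(periodic) == 3L)
  structure(list(lengths = lengths, periodic = periodic),
            class = "simulation_box")
}

#' Minimum-image distance between two points
#'
#' Shortest periodic-image distance across the box's periodic dimensions;
#' plain Euclidean along non-periodic dimensions.
#'
#' @param a,b 3-vectors, nm.
#' @param box a [simulation_box()], or `NULL` for plain Euclidean distance.
#' @return distance in nm.
#' @export
min_image_distance <- function(a, b, box = NULL) {
  d <- as.numeric(a) - as.numeric(b)
  if (!is.null(box)) {
    L <- box$lengths
    p <- box$periodic
    d[p] <- d[p] - L[p] * round(d[p] / L[p])
  }
  sqrt(sum(d^2))
}

# Minimum-image displacement vectors for row-wise point sets (internal).
.min_image_dmat <- function(A, B, box = NULL) {
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  dz <- outer(A[, 3], B[, 3], "-")
  if (!is.null(box)) {
    L <- box$lengths
    p <- box$periodic
    if (p[1]) dx <- dx - L[1] * round(dx / L[1])
    if (p[2]) dy <- dy - L[2] * round(dy / L[2])
    if (p[3]) dz <- dz - L[3] * round(dz / L[3])
  }
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Minimal atom-atom distance between two fullerene balls
#'
#' The minimum over all 60 x 60 periodic atom-atom distances. This is the
#' proximity measure used for distance-cutoff clustering of fullerenes: with
#' centre-of-mass spacing near 1.0 nm and cage radius 0.35 nm the facing-atom
#' gap is about 0.3 nm, below the 0.6 nm clustering cutoff, whereas a
#' COM-based measure could never fall below twice the radius.
#'
#' @param A,B [build_c60()] balls.
#' @param box optional [simulation_box()] for periodic distances.
#' @return minimal distance in nm.
#' @export
min_interball_distance <- function(A, B, box = NULL) {
  stopifnot(inherits(A, "fullerene_ball"), inherits(B, "fullerene_ball"))
  min(.min_image_dmat(A$atom_coords, B$atom_coords, box))
}
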