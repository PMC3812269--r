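#' Global energy minima of small (C60)N clusters
#'
#' Basin-hopping over centre-of-mass coordinates using the single-site
#' orientation-averaged pair potential: random restarts around the running
#' best minimum, each followed by local BFGS descent with analytic gradients.
#' For a radial pair potential with a single minimum near 1.0 nm the global
#' minima for N = 3..6 are the equilateral triangle, tetrahedron, regular
#' trigonal bipyramid and octahedron -- the stacking motifs observed for
#' small fullerene aggregates. Vacuum boundary conditions (no periodic
#' images).
#'
#' @param n_balls cluster size, 3..6 supported (2 works and returns the
#'   dimer).
#' @param params [lj_params()] used when `potential` is built internally.
#' @param n_restarts basin-hopping restarts (default 50).
#' @param seed RNG seed (initial configuration and perturbations).
#' @param potential optional pre-built [build_effective_potential()]; built
#'   with defaults when `NULL`.
#' @param perturb_sd Gaussian perturbation scale between hops, nm.
#' @return object of class `cluster_minimum`: `n_balls`, `com_coords`
#'   (N x 3, nm, centred), `energy` (kJ/mol), `pair_distances` (N x N, nm),
#'   `energy_trace` (best energy after each accepted hop).
#' @export
optimize_cluster <- function(n_balls, params = lj_params(), n_restarts = 50L,
                             seed = 1L, potential = NULL, perturb_sd = 0.3) {
  stopifnot(n_balls >= 2L, n_balls <= 6L, n_restarts >= 1L)
  if (is.null(potential)) {
    potential <- build_effective_potential(params, seed = seed)
  }
  set.seed(seed)
  n <- as.integer(n_balls)

  ener <- function(x) sum(pot_eval(potential, dist(matrix(x, ncol = 3L))))
  grad <- function(x) {
    X <- matrix(x, ncol = 3L)
    G <- matrix(0, n, 3L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      dv <- X[i, ] - X[j, ]
      r <- sqrt(sum(dv^2))
      f <- pot_eval(potential, r, 1L) / r
      G[i, ] <- G[i, ] + f * dv
      G[j, ] <- G[j, ] - f * dv
    }
    as.vector(G)
  }
  # push overlapping pairs apart so local descent never starts inside the wall
  spread_out <- function(X, dmin = potential$r_lo + 0.05) {
    for (it in 1:200) {
      D <- as.matrix(dist(X)); diag(D) <- Inf
      if (min(D) >= dmin) break
      ij <- which(D == min(D), arr.ind = TRUE)[1L, ]
      dv <- X[ij[1], ] - X[ij[2], ]
      r <- sqrt(sum(dv^2))
      u <- if (r < 1e-9) rnorm(3) else dv / r
      push <- (dmin - r) / 2 + 1e-3
      X[ij[1], ] <- X[ij[1], ] + push * u
      X[ij[2], ] <- X[ij[2], ] - push * u
    }
    X
  }
  descend <- function(X) {
    optim(as.vector(X), ener, grad, method = "BFGS",
          control = list(maxit = 2000L, reltol = 1e-15))
  }

  X0 <- spread_out(matrix(rnorm(n * 3L, sd = 0.6), ncol = 3L))
  o <- descend(X0)
  best <- o$value
  bestx <- o$par
  trace <- best
  fails <- 0L
  for (k in seq_len(max(0L, n_restarts - 1L))) {
    Xk <- spread_out(matrix(bestx + rnorm(n * 3L, sd = perturb_sd), ncol = 3L))
    o <- tryCatch(descend(Xk), error = function(e) NULL)
    if (is.null(o)) { fails <- fails + 1L; next }
    if (o$value < best - 1e-12) {
      best <- o$value
      bestx <- o$par
    }
    trace <- c(trace, best)
  }
  if (fails >= n_restarts) stop("optimization-failure: all restarts diverged")

  X <- matrix(bestx, ncol = 3L)
  X <- sweep(X, 2L, colMeans(X))
  D <- as.matrix(dist(X))
  structure(list(n_balls = n, com_coords = X, energy = best,
                 pair_distances = D, energy_trace = trace,
                 seed = as.integer(seed)),
            class = "cluster_minimum")
}

#' @export
print.cluster_minimum <- function(x, ...) {
  d <- sort(x$pair_distances[upper.tri(x$pair_distances)])
  cat(sprintf("<cluster_minimum N=%d> E = %.3f kJ/mol\n", x$n_balls, x$energy))
  cat("  pair distances (nm):", paste(sprintf("%.3f", d), collapse = " "), "\n")
  invisible(x)
}

#' Serialise a cluster minimum to JSON (and optionally XYZ)
#'
#' @param x a `cluster_minimum`.
#' @param path output JSON path.
#' @param xyz_path optional XYZ path for the COM sites.
#' @export
write_cluster_minimum <- function(x, path, xyz_path = NULL) {
  stopifnot(inherits(x, "cluster_minimum"))
  jsonlite::write_json(list(
    n_balls = x$n_balls,
    energy_kj_mol = x$energy,
    com_coords_nm = x$com_coords,
    pair_distances_nm = x$pair_distances
  ), path, auto_unbox = TRUE, digits = 10)
  if (!is.null(xyz_path)) {
    lines <- c(sprintf("%d", x$n_balls), "t= 0",
               sprintf("F %12.6f %12.6f %12.6f", x$com_coords[, 1],
                       x$com_coords[, 2], x$com_coords[, 3]))
    writeLines(lines, xyz_path)
  }
  invisible(path)
}
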