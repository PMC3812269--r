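# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (plain double loops, closed forms, quadrature).

# Naive double-loop LJ sum over all atom pairs (no vectorisation).
brute_lj_sum <- function(A, B, sigma = 0.34, eps = 0.36) {
  e <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      r <- sqrt(sum((A[i, ] - B[j, ])^2))
      e <- e + 4 * eps * ((sigma / r)^12 - (sigma / r)^6)
    }
  }
  e
}

# Naive minimal atom-atom distance, optionally with a rectangular periodic
# box scanned over all 27 images.
brute_min_dist <- function(A, B, lengths = NULL, periodic = c(TRUE, TRUE, TRUE)) {
  best <- Inf
  shifts <- if (is.null(lengths)) list(c(0, 0, 0)) else {
    out <- list()
    rng <- function(k) if (periodic[k]) -1:1 else 0
    for (i in rng(1)) for (j in rng(2)) for (k in rng(3)) {
      out[[length(out) + 1]] <- c(i, j, k) * lengths
    }
    out
  }
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    for (s in shifts) {
      d <- sqrt(sum((A[i, ] - B[j, ] - s)^2))
      if (d < best) best <- d
    }
  }
  best
}

# Girifalco-type continuum potential: 60 atoms smeared uniformly over each
# sphere surface (radius a), atom-atom LJ integrated in closed form.
girifalco_energy <- function(r, a = 0.35, sigma = 0.34, eps = 0.36, n = 60) {
  d <- 2 * a
  s <- r / d
  A <- 4 * eps * sigma^6
  B <- 4 * eps * sigma^12
  alpha <- n^2 * A / (12 * d^6)
  beta <- n^2 * B / (90 * d^12)
  -alpha * (1 / (s * (s - 1)^3) + 1 / (s * (s + 1)^3) - 2 / s^4) +
    beta * (1 / (s * (s - 1)^9) + 1 / (s * (s + 1)^9) - 2 / s^10)
}

# Numerical double-shell quadrature of the same smeared-LJ integral,
# verifying the closed form independently.
girifalco_quadrature <- function(r, a = 0.35, sigma = 0.34, eps = 0.36, n = 60) {
  shellpot <- function(x) {
    f <- function(u) {
      rr <- sqrt(x^2 + a^2 - 2 * a * x * u)
      s6 <- (sigma / rr)^6
      4 * eps * (s6^2 - s6) / 2 * n
    }
    integrate(f, -1, 1, rel.tol = 1e-10)$value
  }
  f2 <- function(u) sapply(u, function(uu) shellpot(sqrt(r^2 + a^2 - 2 * a * r * uu)))
  integrate(f2, -1, 1, rel.tol = 1e-9)$value * n / 2
}

# Canonical polyhedron templates (unit edge) for motif tests.
template_coords <- function(shape) {
  s3 <- sqrt(3)
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, s3 / 2, 0))
  tetra <- rbind(tri, c(0.5, s3 / 6, sqrt(2 / 3)))
  # trigonal bipyramid: equatorial triangle + two apexes
  cen <- colMeans(tri)
  h <- sqrt(2 / 3)
  tb <- rbind(tri, c(cen[1], cen[2], h), c(cen[1], cen[2], -h))
  switch(shape,
    pair = rbind(c(0, 0, 0), c(1, 0, 0)),
    triangle = tri,
    tetrahedron = tetra,
    tb_regular = tb,
    tb_deformed = rbind(tetra, c(0.5, -s3 / 2, 0)),
    octahedron = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1)) / sqrt(2),
    octa_deformed = {
      # bipyramid + sixth ball capping a face of the upper tetrahedron
      face <- tb[c(1, 2, 4), ]
      fc <- colMeans(face)
      nrm <- pracma_cross(face[2, ] - face[1, ], face[3, ] - face[1, ])
      nrm <- nrm / sqrt(sum(nrm^2))
      if (sum(nrm * (fc - colMeans(tb))) < 0) nrm <- -nrm
      rbind(tb, fc + nrm * sqrt(2 / 3))
    },
    stop("unknown shape"))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Small helper: build a frame of rod "lipids" with given head positions and
# unit directors (head + nbead tail beads), plus nothing else.
rod_lipid_frame <- function(heads, dirs, box, nbead = 2, bond = 0.2) {
  n <- nrow(heads)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- seq_len(nbead) * bond
    rows[[i]] <- data.frame(
      x = c(heads[i, 1], heads[i, 1] + dirs[i, 1] * k),
      y = c(heads[i, 2], heads[i, 2] + dirs[i, 2] * k),
      z = c(heads[i, 3], heads[i, 3] + dirs[i, 3] * k),
      label = c("lipid_head", rep("lipid_tail", nbead)),
      molecule_id = i)
  }
  new_frame(do.call(rbind, rows), box)
}

.kB_test <- 0.008314462618

# Pairwise min-image distance matrix for an n x 3 point set.
.min_image_dmat_test <- function(X, box) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    D[i, j] <- D[j, i] <- min_image_distance(X[i, ], X[j, ], box)
  }
  D
}
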