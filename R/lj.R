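#' Lennard-Jones parameters for fullerene carbon
#'
#' Defaults are the neutral LJ carbon parameters used for C60 in the Amber
#' force-field convention: sigma 0.34 nm, epsilon 0.36 kJ/mol.
#'
#' @param sigma LJ cross-section, nm.
#' @param epsilon well depth, kJ/mol.
#' @return object of class `lj_params`.
#' @export
lj_params <- function(sigma = 0.34, epsilon = 0.36) {
  stopifnot(is.finite(sigma), sigma > 0, is.finite(epsilon), epsilon > 0)
  structure(list(sigma = sigma, epsilon = epsilon), class = "lj_params")
}

#' Atomistic LJ pair energy between two C60 balls
#'
#' Full-range (no cutoff) sum of 4*eps*((sigma/r)^12 - (sigma/r)^6) over all
#' 3600 atom pairs.
#'
#' @param A,B `fullerene_ball` objects.
#' @param params [lj_params()].
#' @param box optional [simulation_box()] for periodic distances (vacuum by
#'   default, the convention for cluster energetics).
#' @return energy, kJ/mol.
#' @export
pair_energy_atomistic <- function(A, B, params = lj_params(), box = NULL) {
  stopifnot(inherits(A, "fullerene_ball"), inherits(B, "fullerene_ball"),
            inherits(params, "lj_params"))
  r <- .min_image_dmat(A$atom_coords, B$atom_coords, box)
  if (any(r <= 1e-6)) stop("singular-configuration: atom pair at zero distance")
  s6 <- (params$sigma / r)^6
  sum(4 * params$epsilon * (s6 * s6 - s6))
}

# Orientation-averaged dimer energy at COM separations r, using a fixed set
# of random mutual orientations (common random numbers keep the curve smooth
# in r). Internal work-horse for dimer_minimum / build_effective_potential.
.orientation_avg_energy <- function(r, params, radius, rotations) {
  v <- .trunc_icosa_vertices() * radius
  vapply(r, function(ri) {
    mean(vapply(rotations, function(rr) {
      A <- structure(list(ball_id = 1L, center = c(0, 0, 0),
                          atom_coords = v %*% t(rr[[1]])),
                     class = "fullerene_ball")
      Bc <- v %*% t(rr[[2]])
      B <- structure(list(ball_id = 2L, center = c(ri, 0, 0),
                          atom_coords = sweep(Bc, 2L, c(ri, 0, 0), "+")),
                     class = "fullerene_ball")
      pair_energy_atomistic(A, B, params)
    }, numeric(1)))
  }, numeric(1))
}

.make_rotation_pairs <- function(n_orientations, seed) {
  set.seed(seed)
  lapply(seq_len(n_orientations),
         function(i) list(random_rotation(), random_rotation()))
}

#' Equilibrium separation of the C60 dimer
#'
#' Minimises the orientation-averaged atomistic pair energy over the
#' centre-of-mass separation by bracketed 1-D search. With the default
#' parameters the minimum falls at ~1.0 nm, the known C60-C60 equilibrium
#' distance in vacuum.
#'
#' @param params [lj_params()].
#' @param n_orientations number of random mutual orientations averaged at
#'   each separation (the same draw is reused across separations).
#' @param seed RNG seed for the orientation draw.
#' @param interval search bracket for the separation, nm.
#' @param radius cage radius, nm.
#' @return list with `r_min` (nm) and `e_min` (kJ/mol).
#' @export
dimer_minimum <- function(params = lj_params(), n_orientations = 100L,
                          seed = 1L, interval = c(0.8, 1.3), radius = 0.35) {
  stopifnot(n_orientations >= 1L)
  rots <- .make_rotation_pairs(n_orientations, seed)
  f <- function(r) .orientation_avg_energy(r, params, radius, rots)
  opt <- optimize(f, interval = interval, tol = 1e-5)
  tol_edge <- 1e-3
  if (opt$minimum - interval[1] < tol_edge ||
      interval[2] - opt$minimum < tol_edge) {
    stop("optimization-failure: no interior minimum bracketed in [",
         interval[1], ", ", interval[2], "] nm")
  }
  list(r_min = opt$minimum, e_min = opt$objective)
}

#' Tabulate the orientation-averaged effective pair potential
#'
#' Reduces the 60x60-site atomistic interaction to a single-site radial
#' potential by averaging over random mutual orientations at each grid
#' separation. The table is interpolated with a cubic spline (energy and
#' first derivative continuous); beyond the grid the potential continues as
#' an attractive r^-6 tail matched at the last grid point, and below the grid
#' a linear repulsive wall (slope capped for integrator stability) stands in
#' for the hard core.
#'
#' @param params [lj_params()].
#' @param r_grid increasing separations, nm; minimum must exceed 0.75 nm
#'   (the table must stay clear of the hard-core blow-up).
#' @param n_orientations orientations averaged per grid point.
#' @param seed RNG seed.
#' @param radius cage radius, nm.
#' @param wall_slope repulsive wall slope below the grid, kJ/mol/nm
#'   (negative); also the clamp magnitude used by the Langevin integrator.
#' @return object of class `effective_potential` with fields `separations`,
#'   `energies`, `n_orientations`, `seed`, and spline evaluators.
#' @export
build_effective_potential <- function(params = lj_params(),
                                      r_grid = seq(0.9, 4.0, by = 0.02),
                                      n_orientations = 100L, seed = 1L,
                                      radius = 0.35, wall_slope = -400) {
  stopifnot(all(diff(r_grid) > 0))
  if (min(r_grid) <= 0.75) {
    stop("invalid-grid: r_grid enters the hard-core blow-up region (min must exceed 0.75 nm)")
  }
  rots <- .make_rotation_pairs(n_orientations, seed)
  e <- .orientation_avg_energy(r_grid, params, radius, rots)
  sp <- splinefun(r_grid, e, method = "fmm")
  r_lo <- min(r_grid); r_hi <- max(r_grid)
  v_lo <- sp(r_lo); v_hi <- sp(r_hi)
  slope_lo <- min(sp(r_lo, 1L), wall_slope)  # at least as steep as the cap
  structure(list(
    separations = r_grid, energies = e,
    n_orientations = as.integer(n_orientations), seed = as.integer(seed),
    params = params, radius = radius,
    r_lo = r_lo, r_hi = r_hi, v_lo = v_lo, v_hi = v_hi,
    wall_slope = wall_slope, spline = sp
  ), class = "effective_potential")
}

#' Evaluate an effective potential (energy or radial derivative)
#'
#' @param pot an `effective_potential`.
#' @param r separations, nm.
#' @param deriv 0 for energy (kJ/mol), 1 for dV/dr (kJ/mol/nm).
#' @export
pot_eval <- function(pot, r, deriv = 0L) {
  stopifnot(inherits(pot, "effective_potential"))
  out <- numeric(length(r))
  lo <- r < pot$r_lo
  hi <- r > pot$r_hi
  mid <- !lo & !hi
  if (deriv == 0L) {
    out[mid] <- pot$spline(r[mid])
    out[lo] <- pot$v_lo + pot$wall_slope * (r[lo] - pot$r_lo)
    out[hi] <- pot$v_hi * (pot$r_hi / r[hi])^6
  } else {
    out[mid] <- pmax(pmin(pot$spline(r[mid], 1L), -pot$wall_slope),
                     pot$wall_slope)
    out[lo] <- pot$wall_slope
    out[hi] <- -6 * pot$v_hi * pot$r_hi^6 / r[hi]^7
  }
  out
}

#' @export
print.effective_potential <- function(x, ...) {
  imin <- which.min(x$energies)
  cat(sprintf(
    "<effective_potential> %d points on [%.2f, %.2f] nm, %d orientations (seed %d)\n",
    length(x$separations), x$r_lo, x$r_hi, x$n_orientations, x$seed))
  cat(sprintf("  table minimum %.2f kJ/mol near %.3f nm\n",
              x$energies[imin], x$separations[imin]))
  invisible(x)
}
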