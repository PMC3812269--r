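#' Parameters for the synthetic aggregation simulator
#'
#' Study conditions mirror the reference setup: 6 fullerenes in a box with
#' the lateral dimensions of a 128-lipid DOPC patch, coupled to a 298 K
#' heat bath. The integrator is overdamped (position) Langevin dynamics of
#' single-site particles under the orientation-averaged pair potential;
#' `friction` is the per-mass collision rate gamma (ps^-1) with the C60 mass
#' fixed at 720.66 amu, so the diffusion coefficient is
#' D = kB*T/(m*gamma) -- the default gamma = 6.9 ps^-1 gives
#' D ~ 5e-4 nm^2/ps, the right order for C60 in water.
#'
#' @param n_particles number of fullerene particles.
#' @param box a [simulation_box()].
#' @param temperature K.
#' @param friction gamma, ps^-1.
#' @param timestep ps. The default 0.5 ps resolves the stiff effective-pair
#'   well; larger steps trip the drift diagnostic.
#' @param n_steps integration steps.
#' @param stride output every `stride` steps.
#' @param seed RNG seed (initial placement and thermal noise).
#' @param membrane optional [membrane_well_spec()].
#' @param initial_positions optional n x 3 matrix of starting positions, nm;
#'   when `NULL`, particles are placed >= 2 nm apart (and, with a membrane,
#'   2 nm outside the slab surfaces, split evenly between the two sides).
#' @return object of class `aggregation_params`.
#' @export
aggregation_params <- function(n_particles = 6L,
                               box = simulation_box(c(6.2, 6.2, 9.0)),
                               temperature = 298, friction = 6.9,
                               timestep = 0.5, n_steps = 200000L,
                               stride = 2000L, seed = 1L, membrane = NULL,
                               initial_positions = NULL) {
  stopifnot(timestep > 0, temperature >= 0, friction > 0, n_particles >= 1L)
  if (!is.null(membrane)) stopifnot(inherits(membrane, "membrane_well_spec"))
  structure(list(n_particles = as.integer(n_particles), box = box,
                 temperature = temperature, friction = friction,
                 timestep = timestep, n_steps = as.integer(n_steps),
                 stride = as.integer(stride), seed = as.integer(seed),
                 membrane = membrane, initial_positions = initial_positions),
            class = "aggregation_params")
}

#' Implicit membrane slab for the aggregation simulator
#'
#' A Gaussian double well along z with minima at `|z - center_z| =
#' preferred_depth_offset` (default 1.0 nm, the depth fullerene clusters
#' prefer inside a DOPC bilayer), active within `half_thickness + 2 *
#' well_width` of the slab centre, plus an optional Gaussian barrier at the
#' water-membrane interface.
#'
#' @param center_z slab centre, nm.
#' @param half_thickness nm (default 2.13, half of a 4.26 nm DOPC bilayer).
#' @param preferred_depth_offset well-minimum distance from the centre, nm;
#'   must lie inside the slab.
#' @param well_depth kJ/mol (> 0). Default 20, a literature-scale membrane
#'   partitioning free energy for C60.
#' @param well_width Gaussian width, nm.
#' @param interface_barrier barrier height at `|z - center_z| =
#'   half_thickness`, kJ/mol (default 1, small).
#' @return object of class `membrane_well_spec`.
#' @export
membrane_well_spec <- function(center_z, half_thickness = 2.13,
                               preferred_depth_offset = 1.0, well_depth = 20,
                               well_width = 0.3, interface_barrier = 1) {
  stopifnot(preferred_depth_offset > 0,
            preferred_depth_offset < half_thickness,
            well_depth > 0, well_width > 0, interface_barrier >= 0)
  structure(list(center_z = center_z, half_thickness = half_thickness,
                 preferred_depth_offset = preferred_depth_offset,
                 well_depth = well_depth, well_width = well_width,
                 interface_barrier = interface_barrier),
            class = "membrane_well_spec")
}

#' Simulate fullerene aggregation / membrane partitioning
#'
#' Overdamped Langevin dynamics of `n_particles` single-site fullerenes
#' under the tabulated effective pair potential, with periodic boundaries
#' per the box, hard-core reflection below the table floor, and the optional
#' implicit membrane well. Reproducible under the params seed.
#'
#' The per-step deterministic drift is monitored; if it ever exceeds half
#' the LJ sigma the run aborts with a timestep-too-large error (the thermal
#' noise component is unbounded by construction and is not part of the
#' check).
#'
#' @param params [aggregation_params()].
#' @param potential [build_effective_potential()] table; must cover all
#'   separations the dynamics can reach (reflection handles the core).
#' @return object of class `ball_trajectory`: `times` (ps), `positions`
#'   (list of n x 3 matrices), `box`, `radius`, `params`.
#' @export
simulate_aggregation <- function(params, potential) {
  stopifnot(inherits(params, "aggregation_params"),
            inherits(potential, "effective_potential"))
  n <- params$n_particles
  box <- params$box
  L <- box$lengths
  set.seed(params$seed)

  X0 <- params$initial_positions
  if (is.null(X0)) {
    if (is.null(params$membrane)) {
      X0 <- matrix(runif(n * 3L), n, 3L) %*% diag(L)
      for (it in 1:500) {
        if (n == 1L) break
        D <- as.matrix(dist(X0)); diag(D) <- Inf
        if (min(D) >= 2.0) break
        ij <- which(D == min(D), arr.ind = TRUE)[1L, ]
        X0[ij[1], ] <- runif(3) * L
      }
    } else {
      mw <- params$membrane
      n_up <- ceiling(n / 2)
      side <- c(rep(1, n_up), rep(-1, n - n_up))
      z <- mw$center_z + side * (mw$half_thickness + 2.0)
      X0 <- cbind(matrix(runif(n * 2L), n, 2L) %*% diag(L[1:2]), z)
      for (it in 1:500) {
        if (n == 1L) break
        D <- .min_image_dmat(X0, X0, box); diag(D) <- Inf
        if (min(D) >= 2.0) break
        ij <- which(D == min(D), arr.ind = TRUE)[1L, ]
        X0[ij[1], 1:2] <- runif(2) * L[1:2]
      }
    }
  }
  stopifnot(is.matrix(X0), nrow(X0) == n, ncol(X0) == 3L)

  # dense force table for the C++ kernel
  fine <- seq(potential$r_lo, potential$r_hi, by = 0.001)
  dVg <- pot_eval(potential, fine, 1L)
  mob <- 1 / (.m_c60 * params$friction)  # nm^2 / (kJ/mol) / ps
  kT <- .kB * params$temperature
  mw <- params$membrane

  res <- .langevin_run(
    X0, L, box$periodic, fine, dVg, abs(potential$wall_slope),
    !is.null(mw),
    if (is.null(mw)) 0 else mw$center_z,
    if (is.null(mw)) 0 else mw$half_thickness,
    if (is.null(mw)) 0 else mw$preferred_depth_offset,
    if (is.null(mw)) 0 else mw$well_depth,
    if (is.null(mw)) 0 else mw$well_width,
    if (is.null(mw)) 0 else mw$interface_barrier,
    mob, kT, params$timestep, params$n_steps, params$stride)

  if (res$max_drift > 0.5 * potential$params$sigma) {
    stop(sprintf(
      "timestep-too-large: drift %.3f nm/step exceeds 0.5*sigma = %.3f nm",
      res$max_drift, 0.5 * potential$params$sigma))
  }
  nf <- length(res$times)
  positions <- lapply(seq_len(nf), function(f) {
    matrix(res$frames[((f - 1L) * n * 3L + 1L):(f * n * 3L)], n, 3L,
           byrow = TRUE)
  })
  structure(list(times = res$times, positions = positions, box = box,
                 radius = potential$radius, params = params),
            class = "ball_trajectory")
}

#' @export
print.ball_trajectory <- function(x, ...) {
  cat(sprintf("<ball_trajectory> %d particles, %d frames, t = %g..%g ps\n",
              nrow(x$positions[[1]]), length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Write a ball trajectory as multi-frame XYZ (+ JSON metadata sidecar)
#'
#' @param traj a `ball_trajectory`.
#' @param path XYZ output path.
#' @param meta_path optional JSON sidecar (seed, box, parameters).
#' @export
write_ball_trajectory <- function(traj, path, meta_path = NULL) {
  stopifnot(inherits(traj, "ball_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$times)) {
    X <- traj$positions[[f]]
    writeLines(c(sprintf("%d", nrow(X)), sprintf("t= %g", traj$times[f]),
                 sprintf("F %12.6f %12.6f %12.6f", X[, 1], X[, 2], X[, 3])),
               con)
  }
  if (!is.null(meta_path)) {
    p <- traj$params
    jsonlite::write_json(list(
      n_particles = p$n_particles, temperature_K = p$temperature,
      friction_per_ps = p$friction, timestep_ps = p$timestep,
      n_steps = p$n_steps, stride = p$stride, seed = p$seed,
      box_nm = traj$box$lengths, radius_nm = traj$radius,
      has_membrane_well = !is.null(p$membrane)
    ), meta_path, auto_unbox = TRUE, digits = 10)
  }
  invisible(path)
}

#' Read a ball trajectory written by [write_ball_trajectory()]
#'
#' @param path XYZ path.
#' @param box a [simulation_box()].
#' @param radius cage radius attached to the trajectory, nm.
#' @export
read_ball_trajectory <- function(path, box, radius = 0.35) {
  frames <- read_xyz(path, box)
  structure(list(
    times = vapply(frames, function(f) f$time, numeric(1)),
    positions = lapply(frames, function(f)
      as.matrix(f$atoms[, c("x", "y", "z")])),
    box = box, radius = radius, params = NULL
  ), class = "ball_trajectory")
}
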