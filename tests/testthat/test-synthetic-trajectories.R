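quick_pot <- build_effective_potential(n_orientations = 10, seed = 1)

test_that("fixed seed gives bit-identical trajectories", {
  p <- aggregation_params(n_particles = 4, n_steps = 5000L, stride = 500L,
                          seed = 8)
  t1 <- simulate_aggregation(p, quick_pot)
  t2 <- simulate_aggregation(p, quick_pot)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$times, t2$times)
})

test_that("a single particle at zero temperature does not move", {
  p <- aggregation_params(n_particles = 1, temperature = 0, n_steps = 1000L,
                          stride = 100L, seed = 1)
  traj <- simulate_aggregation(p, quick_pot)
  X0 <- traj$positions[[1]]
  for (X in traj$positions) expect_equal(X, X0, tolerance = 1e-12)
})

test_that("an oversized timestep is caught by the drift diagnostic", {
  X0 <- rbind(c(2.0, 3, 3), c(2.95, 3, 3), c(4.0, 3, 3))
  p <- aggregation_params(n_particles = 3, timestep = 50, n_steps = 200L,
                          stride = 100L, seed = 1, initial_positions = X0)
  expect_error(simulate_aggregation(p, quick_pot), "timestep-too-large")
})

test_that("bulk runs show no systematic z drift beyond diffusion scaling", {
  p <- aggregation_params(n_particles = 6, n_steps = 20000L, stride = 200L,
                          seed = 12, box = simulation_box(c(8, 8, 8),
                                                          periodic = c(TRUE, TRUE, FALSE)))
  traj <- simulate_aggregation(p, quick_pot)
  z0 <- mean(traj$positions[[1]][, 3])
  zT <- mean(traj$positions[[length(traj$positions)]][, 3])
  # diffusion scale of the 6-particle COM over the run
  D <- .kB_test * 298 / (720.66 * 6.9)
  sigma_com <- sqrt(2 * D * max(traj$times) / 6)
  expect_lt(abs(zT - z0), 4 * sigma_com)
})

test_that("aggregated particles sit at the pair-potential minimum separation", {
  pot <- build_effective_potential(n_orientations = 40, seed = 2)
  p <- aggregation_params(n_particles = 4, n_steps = 100000L, stride = 2000L,
                          seed = 5, box = simulation_box(c(5, 5, 5)))
  traj <- simulate_aggregation(p, pot)
  # use the last quarter of the run, contacts only
  late <- traj$positions[seq(ceiling(length(traj$positions) * 0.75),
                             length(traj$positions))]
  r_min <- pot$separations[which.min(pot$energies)]
  contacts <- unlist(lapply(late, function(X) {
    D <- .min_image_dmat_test(X, traj$box)
    d <- D[upper.tri(D)]
    d[d < 1.3]
  }))
  expect_gt(length(contacts), 10)
  expect_equal(mean(contacts), r_min, tolerance = 0.05)
})

test_that("synthetic bilayer recovers its construction targets exactly", {
  spec <- bilayer_spec(target_thickness = 4.26, target_area_per_lipid = 0.599)
  fr <- build_synthetic_bilayer(spec)
  mc <- membrane_center(fr)
  expect_equal(2 * mc$half_thickness, 4.26, tolerance = 1e-9)
  expect_equal(prod(fr$box$lengths[1:2]), 64 * 0.599, tolerance = 1e-9)

  fr2 <- build_synthetic_bilayer(spec)
  expect_identical(fr$atoms, fr2$atoms)  # seeded determinism

  expect_error(build_synthetic_bilayer(bilayer_spec(n_lipids_per_leaflet = 60L)),
               "placement-failure")
})

test_that("infinite tilt concentration aligns every tail director with the normal", {
  fr <- build_synthetic_bilayer(bilayer_spec(tilt_concentration = Inf,
                                             n_lipids_per_leaflet = 16L))
  a <- fr$atoms[fr$atoms$label %in% c("lipid_head", "lipid_tail"), ]
  for (id in unique(a$molecule_id)) {
    m <- a[a$molecule_id == id, ]
    # head-to-last-bead displacement must be vertical (zig-zag is lateral
    # and cancels over an even number of beads)
    expect_lt(abs(m$x[1] - m$x[nrow(m)]), 0.06)
    expect_lt(abs(m$y[1] - m$y[nrow(m)]), 0.06)
    expect_gt(abs(m$z[1] - m$z[nrow(m)]), 1.0)
  }
})

test_that("ball injection honours depth, carves a cavity, and conserves lipids", {
  fr <- build_synthetic_bilayer(bilayer_spec())
  mc <- membrane_center(fr)
  n_lip <- length(unique(fr$atoms$molecule_id[fr$atoms$label == "lipid_head"]))
  ball <- build_c60()

  at0 <- inject_ball_into_bilayer(fr, ball, depth = 0)
  bz <- mean(at0$atoms$z[at0$atoms$label == "fullerene"])
  expect_equal(bz, mc$center_z, tolerance = 1e-9)

  at2 <- inject_ball_into_bilayer(fr, ball, depth = mc$half_thickness + 2.0)
  bz2 <- mean(at2$atoms$z[at2$atoms$label == "fullerene"])
  expect_equal(bz2 - mc$center_z, mc$half_thickness + 2.0, tolerance = 1e-9)

  n_lip2 <- length(unique(at0$atoms$molecule_id[at0$atoms$label == "lipid_head"]))
  expect_identical(n_lip2, n_lip)
  # no head bead left inside the exclusion radius
  heads <- at0$atoms[at0$atoms$label == "lipid_head", ]
  L <- at0$box$lengths
  dxy <- cbind(heads$x - L[1] / 2, heads$y - L[2] / 2)
  dxy <- dxy - sweep(round(sweep(dxy, 2, L[1:2], "/")), 2, L[1:2], "*")
  expect_true(all(sqrt(rowSums(dxy^2)) >= 0.35 + 0.35 - 1e-9))
})
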