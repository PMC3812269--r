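bilayer_fixture <- build_synthetic_bilayer(bilayer_spec())

test_that("membrane centre and half thickness recover the construction geometry", {
  mc <- membrane_center(bilayer_fixture)
  expect_equal(2 * mc$half_thickness, 4.26, tolerance = 1e-9)

  shifted <- bilayer_fixture
  shifted$atoms$z <- shifted$atoms$z + 1
  mc2 <- membrane_center(shifted)
  expect_equal(mc2$center_z, mc$center_z + 1, tolerance = 1e-9)
  expect_equal(mc2$half_thickness, mc$half_thickness, tolerance = 1e-12)

  # heads at z = +-h exactly
  box <- simulation_box(c(4, 4, 10))
  heads <- rbind(c(1, 1, 6.5), c(3, 3, 6.5), c(1, 3, 3.5), c(3, 1, 3.5))
  dirs <- rbind(c(0, 0, -1), c(0, 0, -1), c(0, 0, 1), c(0, 0, 1))
  fr <- rod_lipid_frame(heads, dirs, box)
  mc3 <- membrane_center(fr)
  expect_equal(mc3$center_z, 5)
  expect_equal(mc3$half_thickness, 1.5)

  # monolayer is rejected
  mono <- rod_lipid_frame(heads[1:2, ], dirs[1:2, ], box)
  expect_error(membrane_center(mono), "not-a-bilayer")
})

test_that("insertion depth tracks ball COM relative to the membrane centre", {
  mc <- membrane_center(bilayer_fixture)
  ball <- build_c60()
  for (d in c(0, 1.0, mc$half_thickness + 2.0)) {
    fr <- inject_ball_into_bilayer(bilayer_fixture, ball, depth = d)
    ds <- insertion_depth(list(fr), reference_half_thickness = mc$half_thickness)
    expect_equal(ds$depth, d, tolerance = 1e-9)
  }
  expect_equal(attr(insertion_depth(list(inject_ball_into_bilayer(
    bilayer_fixture, ball, 1)), reference_half_thickness = 2.13),
    "reference_half_thickness"), 2.13)

  # single-site trajectories: signed depth per ball per frame
  traj <- structure(list(times = c(0, 100),
                         positions = list(rbind(c(1, 1, 5.1), c(1, 2, 2.9)),
                                          rbind(c(1, 1, 5.3), c(1, 2, 2.7))),
                         box = simulation_box(c(5, 5, 8)), radius = 0.35,
                         params = NULL), class = "ball_trajectory")
  ds <- insertion_depth(traj, reference_half_thickness = 2.13, center_z = 4)
  expect_equal(ds$depth[ds$time == 0], c(1.1, -1.1), tolerance = 1e-12)
  expect_equal(ds$depth[ds$time == 100], c(1.3, -1.3), tolerance = 1e-12)
})

test_that("density profiles conserve atom counts exactly for every component", {
  ball <- build_c60()
  fr <- inject_ball_into_bilayer(bilayer_fixture, ball, depth = 0)
  for (bw in c(0.07, 0.1, 0.25)) {
    prof <- density_profile(list(fr), bin_width = bw)
    area <- attr(prof, "box_area")
    counts <- table(factor(fr$atoms$label,
                           levels = c("fullerene", "lipid_head",
                                      "lipid_tail", "water")))
    for (comp in names(counts)) {
      expect_equal(sum(prof[[comp]]) * bw * area, as.numeric(counts[[comp]]),
                   tolerance = 1e-9)
    }
  }
  # a ball at the centre peaks the fullerene profile at the zero bin
  prof <- density_profile(list(fr), bin_width = 0.2)
  peak_bin <- prof$bin_center[which.max(prof$fullerene)]
  expect_lt(abs(peak_bin), 0.2)
})

test_that("uniform water fills a flat profile within Poisson fluctuations", {
  set.seed(61)
  n <- 20000
  box <- simulation_box(c(6, 6, 10))
  # thin bilayer to define the centre, plus a uniform water slab well away
  heads <- rbind(c(1, 1, 5.5), c(5, 5, 5.5), c(1, 5, 4.5), c(5, 1, 4.5))
  dirs <- rbind(c(0, 0, -1), c(0, 0, -1), c(0, 0, 1), c(0, 0, 1))
  fr <- rod_lipid_frame(heads, dirs, box)
  water <- data.frame(x = runif(n, 0, 6), y = runif(n, 0, 6),
                      z = runif(n, 7, 9), label = "water",
                      molecule_id = 100L + seq_len(n))
  fr$atoms <- rbind(fr$atoms, water)
  prof <- density_profile(list(fr), components = "water", bin_width = 0.2)
  inner <- prof$water[prof$bin_center > 2.1 & prof$bin_center < 3.9]
  lambda <- n / 10  # expected count per fully-covered bin
  counts <- inner * attr(prof, "box_area") * 0.2
  expect_true(all(abs(counts - lambda) <= 3 * sqrt(lambda)))
})

test_that("order parameter hits the aligned and isotropic closed-form limits", {
  aligned <- build_synthetic_bilayer(bilayer_spec(tilt_concentration = Inf,
                                                  n_lipids_per_leaflet = 16L))
  op <- order_parameter(aligned)
  # the zig-zag tilts the principal axis ~1.5 deg off the director, so the
  # aligned limit is met to ~1e-3 rather than machine precision
  expect_equal(op$S_zz, 1, tolerance = 5e-3)
  expect_equal(op$S_cd, 0.5, tolerance = 5e-3)
  expect_equal(op$S_xx + op$S_yy + op$S_zz, 0, tolerance = 1e-10)

  set.seed(62)
  n <- 20000
  tpl <- rbind(c(0, 0, 0), c(0.1, 0, 0.3), c(-0.05, 0.15, 0.55))
  rots <- random_rotation(n)
  coords <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) coords[(3 * i - 2):(3 * i), ] <- tpl %*% t(rots[[i]])
  coords[, 3] <- coords[, 3] + rep(rep(c(2, -2), length.out = n), each = 3)
  coords[, 1] <- coords[, 1] + rep(runif(n, 0, 50), each = 3)
  coords[, 2] <- coords[, 2] + rep(runif(n, 0, 50), each = 3)
  iso <- new_frame(data.frame(
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    label = rep(c("lipid_head", "lipid_tail", "lipid_tail"), n),
    molecule_id = rep(seq_len(n), each = 3)),
    simulation_box(c(50, 50, 10)))
  op_iso <- order_parameter(iso)
  # isotropic averages vanish like 1/sqrt(n); 0.02 at 2e4 samples
  expect_lt(abs(op_iso$S_xx), 0.02)
  expect_lt(abs(op_iso$S_yy), 0.02)
  expect_lt(abs(op_iso$S_zz), 0.02)
  expect_lt(abs(op_iso$S_cd), 0.02)
  expect_equal(op_iso$S_xx + op_iso$S_yy + op_iso$S_zz, 0, tolerance = 1e-10)
})

test_that("order parameter recovers the tilt distribution of the generator", {
  kappa <- 5
  fr <- build_synthetic_bilayer(bilayer_spec(n_lipids_per_leaflet = 400L,
                                             tilt_concentration = kappa,
                                             seed = 63))
  op <- order_parameter(fr)
  # closed-form von Mises-Fisher second moment: <cos^2> = 1 - 2 L(k) / k
  Lk <- 1 / tanh(kappa) - 1 / kappa
  cos2 <- 1 - 2 * Lk / kappa
  S_zz_pred <- (3 * cos2 - 1) / 2
  se <- 3 / sqrt(op$n_lipids)  # generous sampling bound
  expect_equal(op$S_zz, S_zz_pred, tolerance = se)
  expect_equal(op$S_cd, S_zz_pred / 2, tolerance = se)
})

test_that("collinear molecules trigger the degeneracy warning", {
  box <- simulation_box(c(4, 4, 10))
  heads <- rbind(c(1, 1, 6.5), c(3, 3, 6.5), c(1, 3, 3.5), c(3, 1, 3.5))
  dirs <- rbind(c(0, 0, -1), c(0, 0, -1), c(0, 0, 1), c(0, 0, 1))
  fr <- rod_lipid_frame(heads, dirs, box)  # straight rods: degenerate x/y
  expect_warning(order_parameter(fr), "degenerate inertia tensor")
})

test_that("grid thickness and APL recover the flat-bilayer targets", {
  g <- grid_thickness_apl(bilayer_fixture, grid_n = 20)
  expect_true(all(abs(g$thickness_map - 4.26) < 1e-9))
  expect_equal(g$mean_apl_top, 0.599, tolerance = 1e-9)
  expect_equal(g$mean_apl_bottom, 0.599, tolerance = 1e-9)
  # per-leaflet areas tile the box exactly
  expect_equal(sum(g$apl_top), prod(bilayer_fixture$box$lengths[1:2]),
               tolerance = 1e-9)
  # on the uniform 8x8 lattice with a commensurate grid every lipid owns
  # exactly 4 cells, i.e. the same area
  g16 <- grid_thickness_apl(bilayer_fixture, grid_n = 16)
  expect_true(all(abs(g16$apl_top - 0.599) < 1e-9))
  expect_true(all(abs(g16$apl_bottom - 0.599) < 1e-9))

  # grid refinement changes the leaflet means by < 1% on a jittered bilayer
  fr <- build_synthetic_bilayer(bilayer_spec(xy_jitter = 0.08, seed = 3))
  g1 <- grid_thickness_apl(fr, grid_n = 16)
  g2 <- grid_thickness_apl(fr, grid_n = 32)
  expect_lt(abs(g2$mean_thickness - g1$mean_thickness) / g1$mean_thickness, 0.01)
  expect_lt(abs(g2$mean_apl_top - g1$mean_apl_top) / g1$mean_apl_top, 0.01)
})

test_that("grid maps are invariant under periodic xy translation", {
  fr <- build_synthetic_bilayer(bilayer_spec(xy_jitter = 0.08, seed = 4))
  g0 <- grid_thickness_apl(fr, grid_n = 16)
  L <- fr$box$lengths
  shift <- c(3, 5) * (L[1:2] / 16)  # whole cells, so maps shift cyclically
  fr2 <- fr
  fr2$atoms$x <- (fr2$atoms$x + shift[1]) %% L[1]
  fr2$atoms$y <- (fr2$atoms$y + shift[2]) %% L[2]
  g1 <- grid_thickness_apl(fr2, grid_n = 16)
  expect_equal(sort(as.vector(g1$thickness_map)),
               sort(as.vector(g0$thickness_map)), tolerance = 1e-9)
  expect_equal(sort(unname(g1$apl_top)), sort(unname(g0$apl_top)),
               tolerance = 1e-9)
  expect_equal(g1$mean_thickness, g0$mean_thickness, tolerance = 1e-9)
})
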