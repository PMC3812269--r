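test_that("cutoff clustering joins touching balls and keeps distant ones apart", {
  # two cages at 1.0 nm COM spacing: atom-atom gap ~0.3 nm < 0.6 nm cutoff
  set.seed(51)
  A <- build_c60(center = c(0, 0, 0), rotation = random_rotation(), ball_id = 1)
  B <- build_c60(center = c(1, 0, 0), rotation = random_rotation(), ball_id = 2)
  gap <- brute_min_dist(A$atom_coords, B$atom_coords)
  expect_lt(gap, 0.6)
  ca <- cluster_frame(list(A, B))
  expect_length(ca$partition, 1L)
  expect_setequal(ca$partition[[1]], c(1L, 2L))

  C <- build_c60(center = c(5, 0, 0), ball_id = 3)
  ca2 <- cluster_frame(list(A, C))
  expect_length(ca2$partition, 2L)

  # chain A-B-C: transitive closure makes one 3-cluster
  D3 <- build_c60(center = c(2, 0, 0), rotation = random_rotation(), ball_id = 3)
  ca3 <- cluster_frame(list(A, B, D3))
  expect_length(ca3$partition, 1L)
  expect_setequal(ca3$partition[[1]], 1:3)
  # ...while A and C alone are not in contact
  expect_gt(min_interball_distance(A, D3), 0.6)
})

test_that("clustering partition is a disjoint cover, invariant to relabeling and rigid motion", {
  set.seed(52)
  centers <- rbind(c(0, 0, 0), c(1, 0, 0), c(4, 4, 0), c(4, 5, 0), c(2, 2, 2))
  balls <- lapply(1:5, function(i)
    build_c60(center = centers[i, ], rotation = random_rotation(), ball_id = i))
  ca <- cluster_frame(balls)
  expect_setequal(unlist(ca$partition), 1:5)
  expect_identical(sum(lengths(ca$partition)), 5L)

  canon <- function(p) sort(vapply(p, function(s) paste(sort(s), collapse = "-"), ""))
  # relabel
  perm <- c(3, 1, 5, 2, 4)
  balls_p <- lapply(1:5, function(i) { b <- balls[[perm[i]]]; b })
  ca_p <- cluster_frame(balls_p)
  expect_identical(canon(ca_p$partition), canon(ca$partition))
  # rigid motion of the whole frame
  R <- random_rotation(); t <- c(1, -2, 0.5)
  balls_r <- lapply(balls, function(b) {
    b$atom_coords <- sweep(b$atom_coords %*% t(R), 2, t, "+")
    b$center <- as.numeric(R %*% b$center + t)
    b
  })
  expect_identical(canon(cluster_frame(balls_r)$partition), canon(ca$partition))
})

test_that("raising the cutoff never shrinks the largest cluster", {
  set.seed(53)
  X <- matrix(runif(24, 0, 4), 8, 3)
  box <- simulation_box(c(4, 4, 4))
  sizes <- vapply(seq(0.1, 2.0, by = 0.1), function(co) {
    max(lengths(cluster_frame(X, cutoff = co, box = box)$partition))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("largest-cluster series block-averages per-frame component sizes", {
  # six balls fully clustered in every frame -> constant 6
  hex <- optimize_cluster(6, n_restarts = 10, seed = 1,
                          potential = build_effective_potential(
                            n_orientations = 10, seed = 1))
  traj6 <- structure(list(
    times = seq(0, 4000, by = 500),
    positions = rep(list(hex$com_coords + 3), 9),
    box = simulation_box(c(10, 10, 10)), radius = 0.35, params = NULL),
    class = "ball_trajectory")
  s6 <- largest_cluster_series(traj6, block = 1000)
  expect_true(all(s6$largest_size == 6))

  # all singletons -> constant 1
  far <- matrix(c(1, 1, 1, 5, 5, 5, 9, 9, 1), 3, 3, byrow = TRUE)
  traj1 <- structure(list(times = c(0, 500, 1000), positions = rep(list(far), 3),
                          box = simulation_box(c(12, 12, 12)), radius = 0.35,
                          params = NULL), class = "ball_trajectory")
  expect_true(all(largest_cluster_series(traj1)$largest_size == 1))

  # mixed block: two frames at size 2, two at 4 -> block mean 3
  pairs2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(5, 5, 0), c(6, 5, 0))
  quad4 <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  trajm <- structure(list(
    times = c(0, 250, 500, 750),
    positions = list(pairs2 + 2, pairs2 + 2, quad4 + 2, quad4 + 2),
    box = simulation_box(c(12, 12, 12)), radius = 0.35, params = NULL),
    class = "ball_trajectory")
  sm <- largest_cluster_series(trajm, block = 1000)
  expect_equal(sm$largest_size, 3)

  expect_error(largest_cluster_series(list()), "invalid-input")
})

test_that("motif classification matches all template polyhedra", {
  cases <- c(pair = "pair",
             triangle = "equilateral_triangle",
             tetrahedron = "tetrahedron",
             tb_regular = "trigonal_bipyramid_regular",
             tb_deformed = "trigonal_bipyramid_deformed",
             octahedron = "octahedron_regular",
             octa_deformed = "octahedron_deformed")
  for (nm in names(cases)) {
    expect_identical(motif_classify(template_coords(nm)), cases[[nm]],
                     label = nm)
  }
  # scale invariance: templates at the ~1.0 nm contact distance
  expect_identical(motif_classify(template_coords("triangle") * 1.0),
                   "equilateral_triangle")
  # breaking one bipyramid contact demotes regular -> deformed
  tb <- template_coords("tb_regular")
  expect_identical(motif_classify(template_coords("tb_deformed")),
                   "trigonal_bipyramid_deformed")
  # random blobs are irregular
  set.seed(54)
  expect_identical(motif_classify(matrix(runif(15, 0, 3), 5, 3)), "irregular")
})

test_that("labels are stable under small coordinate noise", {
  shapes <- c(pair = "pair", triangle = "equilateral_triangle",
              tetrahedron = "tetrahedron",
              tb_regular = "trigonal_bipyramid_regular",
              octahedron = "octahedron_regular")
  set.seed(55)
  for (nm in names(shapes)) {
    X <- template_coords(nm)
    d0 <- min(dist(X))
    ok <- 0L
    for (t in 1:1000) {
      Xn <- X + matrix(rnorm(length(X), sd = 0.01 * d0), nrow(X), 3)
      if (motif_classify(Xn) == shapes[[nm]]) ok <- ok + 1L
    }
    expect_gte(ok, 990L)
  }
})

test_that("nucleus lifetimes are run lengths ending in growth, with censoring", {
  mk <- function(sizes) structure(
    data.frame(block_time = seq_along(sizes) * 1000 - 500,
               largest_size = sizes),
    class = c("cluster_size_series", "data.frame"), block = 1000)

  lt <- nucleus_lifetimes(mk(c(1, 1, 2, 2, 2, 4, 4)))
  expect_identical(nrow(lt), 1L)
  expect_equal(lt$duration, 3000)
  expect_false(lt$censored)

  lt2 <- nucleus_lifetimes(mk(c(1, 2, 3, 2, 3)))
  expect_identical(nrow(lt2), 1L)
  expect_true(lt2$censored)

  expect_identical(nrow(nucleus_lifetimes(mk(rep(1, 6)))), 0L)
})
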