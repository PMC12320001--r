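test_that("random cylinder generation hits the target CBV and is reproducible", {
  spec3 <- voxel_spec(3L, 0.1, "continuous")
  cyl <- make_random_cylinders_3d(spec3, 1e-3, 0.02, 1e-6, seed = 7)
  est <- compute_cbv(cyl, spec3, n_samples = 1e5, seed = 42)
  expect_gte(as.numeric(est), 0.018)
  expect_lte(as.numeric(est), 0.022)
  expect_identical(cyl, make_random_cylinders_3d(spec3, 1e-3, 0.02, 1e-6, seed = 7))
  expect_equal(nrow(make_random_cylinders_3d(spec3, 1e-3, 0, 1e-6, seed = 1)), 0L)

  # 400-cylinder configuration: 2% CBV in a 2D voxel sized for 400 vessels
  W400 <- sqrt(400 * pi * 1e-6 / 0.02)
  spec2 <- voxel_spec(2L, W400, "continuous")
  cyl2 <- make_random_cylinders_2d(spec2, 1e-3, 0.02, 1e-6, seed = 3)
  expect_gt(nrow(cyl2), 300)
  est2 <- compute_cbv(cyl2, spec2, n_samples = 1e5, seed = 43)
  expect_gte(as.numeric(est2), 0.018)
  expect_lte(as.numeric(est2), 0.022)
})

test_that("2D effective field orientations follow the 3D-uniform angle law", {
  # cos(theta) of the per-cylinder field direction should be uniform on [-1,1]
  W400 <- sqrt(400 * pi * 1e-6 / 0.02)
  spec2 <- voxel_spec(2L, W400, "continuous")
  ct <- unlist(lapply(1:4, function(s) {
    cos(make_random_cylinders_2d(spec2, 1e-3, 0.02, 1e-6, seed = s)$theta)
  }))
  expect_gt(length(ct), 1000)
  ks <- suppressWarnings(stats::ks.test(ct, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
  ph <- unlist(lapply(1:4, function(s) {
    make_random_cylinders_2d(spec2, 1e-3, 0.02, 1e-6, seed = s)$phi0
  }))
  expect_true(all(ph >= 0 & ph < 2 * pi))
})

test_that("3D cylinder axes are uniform on the sphere", {
  spec3 <- voxel_spec(3L, 0.05, "continuous")
  ct <- unlist(lapply(1:6, function(s) {
    p <- make_random_cylinders_3d(spec3, 0.5e-3, 0.02, 1e-6, seed = s)
    p$dz  # axis_dir . B0_dir for B0 along z
  }))
  expect_gt(length(ct), 500)
  ks <- suppressWarnings(stats::ks.test(ct, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("CBV estimator matches closed forms and union semantics", {
  spec2 <- voxel_spec(2L, 0.1, "continuous")
  empty_set <- cylinders_2d(numeric(0), matrix(numeric(0), 0, 2),
                            numeric(0), numeric(0), numeric(0))
  expect_identical(as.numeric(compute_cbv(empty_set, spec2)), 0)

  # centered circle with R = W/2: area fraction pi/4
  circ <- one_cyl2d(W = 0.1, R = 0.05)
  est <- compute_cbv(circ, spec2, n_samples = 1e5, seed = 2)
  expect_lt(abs(as.numeric(est) - pi / 4), 3 * attr(est, "se"))

  # centered sphere with R = W/4: volume fraction (4/3) pi (1/4)^3
  spec3 <- voxel_spec(3L, 0.1, "continuous")
  sph <- one_sph3d(W = 0.1, R = 0.025)
  est3 <- compute_cbv(sph, spec3, n_samples = 1e5, seed = 2)
  expect_lt(abs(as.numeric(est3) - 4 / 3 * pi / 64), 3 * attr(est3, "se"))

  # two coincident spheres cover the same fraction as one
  two <- spheres_3d(c(0.025, 0.025), rbind(rep(0.05, 3), rep(0.05, 3)), 1e-6)
  est_two <- compute_cbv(two, spec3, n_samples = 1e5, seed = 2)
  expect_equal(as.numeric(est_two), as.numeric(est3), tolerance = 1e-12)
})

test_that("CBV estimate converges to the closed form as n_samples grows", {
  spec2 <- voxel_spec(2L, 0.1, "continuous")
  circ <- one_cyl2d(W = 0.1, R = 0.05)
  err <- vapply(c(1e4, 1e5, 1e6), function(n) {
    abs(as.numeric(compute_cbv(circ, spec2, n_samples = n, seed = 5)) - pi / 4)
  }, numeric(1))
  # ~ n^(-1/2): two decades of n should shrink the error by ~10x
  expect_lt(err[3], err[1])
})

test_that("discretization labels grid-element centers correctly", {
  spec <- voxel_spec(2L, 0.1, "gridded", N = 500)
  gv <- discretize_voxel(one_cyl2d(W = 0.1, R = 0.025), spec)
  frac <- mean(gv$label > 0L)
  expect_lt(abs(frac - pi / 16) / (pi / 16), 0.01)
  # element centers at (i + 1/2) dx: the element containing the center of a
  # centered circle is labelled
  expect_identical(gv$label[250, 250], 1L)

  empty_set <- cylinders_2d(numeric(0), matrix(numeric(0), 0, 2),
                            numeric(0), numeric(0), numeric(0))
  gv0 <- discretize_voxel(empty_set, spec)
  expect_true(all(gv0$label == 0L))

  # perturber smaller than one grid element: zero labels plus warnings
  tiny_spec <- voxel_spec(2L, 0.1, "gridded", N = 10)
  w <- testthat::capture_warnings(gvt <- discretize_voxel(
    cylinders_2d(1e-4, c(0.0501, 0.0501), pi / 2, 0, 1e-6), tiny_spec))
  expect_true(any(grepl("6 are recommended", w)))
  expect_true(any(grepl("undersamples", w)))
  expect_true(all(gvt$label == 0L))
})

test_that("sampling check enforces the 6-elements-across-diameter rule", {
  spec <- voxel_spec(2L, 0.1, "gridded", N = 100)  # dx = 1 um
  expect_length(check_sampling(spec, one_cyl2d(R = 1e-3)), 1L)   # 2 elements
  expect_length(check_sampling(spec, one_cyl2d(R = 3e-3)), 0L)   # 6 elements
  cont <- voxel_spec(2L, 0.1, "continuous")
  expect_length(check_sampling(cont, one_cyl2d(R = 1e-3)), 0L)
})

test_that("generation fails loudly when the target is unreachable", {
  spec2 <- voxel_spec(2L, 0.1, "continuous")
  expect_error(
    make_random_cylinders_2d(spec2, 1e-3, 0.5, 1e-6, seed = 1,
                             max_perturbers = 10),
    "cap of 10")
})

test_that("perturber constructors validate invariants", {
  expect_error(cylinders_2d(-1e-3, c(0, 0), pi / 2, 0, 1e-6), "radius")
  expect_error(cylinders_2d(1e-3, c(0, 0), pi / 2, 0, 1e-6, perm = 1.5), "perm")
  expect_error(cylinders_3d(1e-3, c(0, 0, 0), c(0, 0, 2), 1e-6), "unit")
  expect_error(voxel_spec(3L, 0.1, B0_dir = c(1, 1, 1) * 2), "unit")
  expect_error(voxel_spec(2L, 0.1, "gridded", N = 1), "N >= 2")
})
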