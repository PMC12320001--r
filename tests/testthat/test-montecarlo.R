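test_that("spin initialization respects placement and is reproducible", {
  spec <- voxel_spec(2L, 0.1, "continuous")
  circ <- one_cyl2d(W = 0.1, R = 0.02)
  ens <- init_spins(20000, spec, circ, seed = 1)
  expect_equal(colMeans(ens$pos), c(0.05, 0.05),
               tolerance = 3 * (0.1 / sqrt(12)) / sqrt(20000) / 0.05)
  expect_true(all(ens$pos >= 0 & ens$pos < 0.1))
  expect_identical(ens$mxy, complex(real = rep(0, 20000)))
  expect_identical(ens$mz, rep(1, 20000))

  ev <- init_spins(5000, spec, circ, seed = 2, placement = "ev_only")
  expect_true(all(ev$label == 0L))
  iv <- init_spins(5000, spec, circ, seed = 2, placement = "iv_only")
  expect_true(all(iv$label > 0L))

  expect_identical(init_spins(100, spec, circ, seed = 9),
                   init_spins(100, spec, circ, seed = 9))

  empty <- cylinders_2d(numeric(0), matrix(numeric(0), 0, 2),
                        numeric(0), numeric(0), numeric(0))
  expect_error(init_spins(10, spec, empty, seed = 1, placement = "iv_only"),
               "placement")
})

test_that("diffusion steps have the right variance and wrap periodically", {
  spec <- voxel_spec(2L, 0.1, "continuous")
  cfg <- diffusion_config(D = 1e-3, dt = 2e-4)
  ens <- init_spins(50000, spec, NULL, seed = 3)
  old <- ens$pos
  set.seed(10)
  ens <- mc_step(ens, cfg, NULL)
  disp <- attr(ens, "disp")
  v <- var(as.vector(disp))
  expect_lt(abs(v - 4e-7) / 4e-7, 0.02)  # per-axis variance 2 D dt
  # wrap = modular arithmetic on each axis
  expect_equal(ens$pos, (old + disp) %% 0.1, tolerance = 1e-15)

  # D = 0 leaves everything in place
  circ <- one_cyl2d(W = 0.1, R = 0.02)
  e0 <- init_spins(100, spec, circ, seed = 4)
  e1 <- mc_step(e0, diffusion_config(0, 1e-3), circ)
  expect_identical(e1$pos, e0$pos)
  expect_identical(e1$label, e0$label)
})

test_that("impermeable walls are never crossed; permeable walls are free", {
  spec <- voxel_spec(2L, 0.02, "continuous")
  circ <- one_cyl2d(W = 0.02, R = 5e-3, perm = 0)
  cfg <- diffusion_config(1e-3, 2e-4)
  ens <- init_spins(2000, spec, circ, seed = 5)
  lab0 <- ens$label
  set.seed(11)
  for (i in 1:50) {
    ens <- mc_step(ens, cfg, circ)
    expect_identical(ens$label, lab0)
  }

  open <- one_cyl2d(W = 0.02, R = 5e-3, perm = 1)
  ens2 <- init_spins(2000, spec, open, seed = 5)
  changed <- FALSE
  set.seed(11)
  for (i in 1:10) {
    before <- ens2$label
    ens2 <- mc_step(ens2, cfg, open)
    if (any(ens2$label != before)) changed <- TRUE
  }
  expect_true(changed)
  expect_identical(ens2$n_stuck, 0L)  # perm = 1 never needs resampling
})

test_that("resampling at walls does not introduce drift", {
  spec <- voxel_spec(2L, 0.02, "continuous")
  circ <- one_cyl2d(W = 0.02, R = 5e-3, perm = 0)
  cfg <- diffusion_config(1e-3, 2e-4)
  ens <- init_spins(20000, spec, circ, seed = 6)
  set.seed(12)
  tot <- matrix(0, 20000, 2)
  for (i in 1:10) {
    ens <- mc_step(ens, cfg, circ)
    tot <- tot + attr(ens, "disp")
  }
  sig <- cfg$sigma * sqrt(10) / sqrt(20000)
  expect_lt(abs(mean(tot[, 1])), 4 * sig)
  expect_lt(abs(mean(tot[, 2])), 4 * sig)
})

test_that("free-diffusion MSD grows linearly at rate 2 ndim D t", {
  spec <- voxel_spec(2L, 0.05, "continuous")
  cfg <- diffusion_config(1e-3, 2e-4)
  n <- 20000
  ens <- init_spins(n, spec, NULL, seed = 7)
  set.seed(13)
  unwrapped <- matrix(0, n, 2)
  msd <- numeric(50)
  for (i in 1:50) {
    ens <- mc_step(ens, cfg, NULL)
    unwrapped <- unwrapped + attr(ens, "disp")
    msd[i] <- mean(rowSums(unwrapped^2))
  }
  t <- (1:50) * cfg$dt
  slope <- coef(lm(msd ~ t + 0))[[1]]
  expect_lt(abs(slope - 4 * 1e-3) / (4 * 1e-3), 0.05)
})

test_that("field sampling matches its source on both paths", {
  spec <- voxel_spec(2L, 0.1, "gridded", N = 50)
  circ <- one_cyl2d(W = 0.1, R = 0.02)
  fg <- analytic_field_grid(circ, spec)
  # a spin exactly at an element center sees exactly the grid value
  ctr <- grid_centers(spec)
  ens <- list(pos = ctr[c(1, 777, 1200), , drop = FALSE])
  got <- sample_field(ens, fg)
  expect_identical(got, as.vector(fg$values)[c(1, 777, 1200)])
  # continuous sampling equals the closed form
  ens2 <- list(pos = rbind(c(0.052, 0.05), c(0.03, 0.07)))
  expect_equal(sample_field(ens2, circ, B0 = 3),
               analytic_field(ens2$pos, circ, 3), tolerance = 1e-15)
})

test_that("gridded and continuous field sampling agree on a well-sampled voxel", {
  spec <- voxel_spec(2L, 0.1, "gridded", N = 800)  # 32 elements across 2R
  circ <- one_cyl2d(W = 0.1, R = 0.02)
  fg <- analytic_field_grid(circ, spec)
  set.seed(14)
  pos <- matrix(runif(2e4, 0, 0.1), ncol = 2)
  keep <- (pos[, 1] - 0.05)^2 + (pos[, 2] - 0.05)^2 > (0.021)^2
  pos <- pos[keep, ]
  ens <- list(pos = pos)
  fgv <- sample_field(ens, fg)
  fcv <- sample_field(ens, circ, B0 = 3)
  expect_lt(sqrt(mean((fgv - fcv)^2)) / sqrt(mean(fcv^2)), 0.05)
})
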