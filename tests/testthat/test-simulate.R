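test_that("an empty voxel gives a constant signal equal to the site count", {
  spec <- voxel_spec(2L, 0.05, "continuous")
  empty <- cylinders_2d(numeric(0), matrix(numeric(0), 0, 2),
                        numeric(0), numeric(0), numeric(0))
  sq <- build_sequence("GE", 0.01, 5e-4)
  sig <- run_simulation(sim_config("2D-CTN-CYL-ANA-MC", spec, sq,
                                   perturbers = empty, D = 1e-3,
                                   nspins = 500, seed = 1))
  expect_equal(Mod(sig$total), rep(500, 21), tolerance = 1e-12)
})

test_that("a spin echo perfectly refocuses static dephasing", {
  gm <- small_gm(seed = 2)
  sq <- build_sequence("SE", 0.02, 5e-4)
  sig <- run_simulation(sim_config("2D-CTN-CYL-ANA-MC", gm$spec, sq,
                                   perturbers = gm$perturbers, D = 0,
                                   nspins = 1000, seed = 3))
  n <- length(sig$time)
  expect_equal(Mod(sig$total[n]) / Mod(sig$total[1]), 1, tolerance = 1e-9)
  # mid-sequence the static dephasing is visible
  expect_lt(Mod(sig$total[n / 2]) / Mod(sig$total[1]), 0.999)

  ge <- run_simulation(sim_config("2D-CTN-CYL-ANA-MC", gm$spec,
                                  build_sequence("GE", 0.02, 5e-4),
                                  perturbers = gm$perturbers, D = 0,
                                  nspins = 1000, seed = 3))
  expect_lt(Mod(ge$total[n]) / Mod(ge$total[1]), 1)
})

test_that("MC on fixed grid sites with D = 0 equals DD without diffusion", {
  gm <- small_gm(seed = 4)
  gspec <- voxel_spec(2L, gm$spec$W, "gridded", N = 60, B0 = 3)
  gv <- suppressWarnings(discretize_voxel(gm$perturbers, gspec))
  fg <- analytic_field_grid(gm$perturbers, gspec)
  sq <- build_sequence("GE", 0.01, 5e-4)

  dd <- run_simulation(sim_config("2D-GRD-CYL-ANA-DD", gspec, sq,
                                  perturbers = gm$perturbers, voxel = gv,
                                  D = 0, seed = 5))

  # drive the Monte Carlo machinery by hand with one spin per grid element
  mxy <- rep(complex(real = 0), gspec$N^2)
  mz <- rep(1, gspec$N^2)
  lab <- as.vector(gv$label)
  dbz <- as.vector(fg$values)
  rec <- complex(21)
  for (j in 0:20) {
    if (j == 0) {
      r <- apply_rf(mxy, mz, sq$pulses[[1]])
      mxy <- r$mxy; mz <- r$mz
    } else {
      e <- evolve_step(mxy, mz, dbz, sq$dt)
      mxy <- e$mxy; mz <- e$mz
    }
    rec[j + 1] <- sum_signal(mxy, lab)[["total"]]
  }
  expect_equal(Mod(dd$total), Mod(rec), tolerance = 1e-9)
})

test_that("magnitude is bounded by the site count and T2 decay is exact", {
  gm <- small_gm(seed = 6)
  sq <- build_sequence("SE", 0.02, 5e-4)
  sig <- run_simulation(sim_config("2D-CTN-CYL-ANA-MC", gm$spec, sq,
                                   perturbers = gm$perturbers, D = 1e-3,
                                   nspins = 800, seed = 7))
  expect_true(all(Mod(sig$total) <= 800 * (1 + 1e-12)))
  expect_true(all(Mod(sig$total) <= Mod(sig$iv) + Mod(sig$ev) + 1e-9))

  empty <- cylinders_2d(numeric(0), matrix(numeric(0), 0, 2),
                        numeric(0), numeric(0), numeric(0))
  spec <- voxel_spec(2L, 0.05, "continuous")
  t2 <- 0.03
  dec <- run_simulation(sim_config("2D-CTN-CYL-ANA-MC", spec,
                                   build_sequence("GE", 0.01, 5e-4),
                                   perturbers = empty, D = 1e-3, nspins = 400,
                                   tissue = list(t2 = t2), seed = 8))
  expect_equal(Mod(dec$total), 400 * exp(-dec$time / t2), tolerance = 1e-9)
})

test_that("doubling the susceptibility doubles every accumulated phase", {
  gm <- small_gm(seed = 9)
  sq <- build_sequence("GE", 0.005, 5e-4)
  base <- sim_config("2D-CTN-CYL-ANA-MC", gm$spec, sq,
                     perturbers = gm$perturbers, D = 0, nspins = 1, seed = 10)
  s1 <- run_simulation(base)
  p2 <- gm$perturbers; p2$dchi <- 2 * p2$dchi
  cfg2 <- sim_config("2D-CTN-CYL-ANA-MC", gm$spec, sq, perturbers = p2,
                     D = 0, nspins = 1, seed = 10)
  s2 <- run_simulation(cfg2)
  # single static spin: accumulate per-step phase increments (each << pi)
  n <- length(s1$total)
  ph1 <- cumsum(Arg(s1$total[-1] / s1$total[-n]))
  ph2 <- cumsum(Arg(s2$total[-1] / s2$total[-n]))
  expect_equal(ph2, 2 * ph1, tolerance = 1e-9)
})

test_that("simulations are deterministic given the seed", {
  gm <- small_gm(seed = 11)
  sq <- build_sequence("SE", 0.01, 5e-4)
  cfg <- sim_config("2D-CTN-CYL-ANA-MC", gm$spec, sq,
                    perturbers = gm$perturbers, D = 1e-3, nspins = 300,
                    seed = 12)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$total, s2$total)
  s3 <- run_simulation(sim_config("2D-CTN-CYL-ANA-MC", gm$spec, sq,
                                  perturbers = gm$perturbers, D = 1e-3,
                                  nspins = 300, seed = 13))
  expect_false(identical(s1$total, s3$total))
})

test_that("incompatible method/geometry configurations are rejected", {
  gm <- small_gm(seed = 14)
  sq <- build_sequence("GE", 0.005, 5e-4)
  expect_error(run_simulation(sim_config("2D-GRD-CYL-ANA-DD", gm$spec, sq,
                                         perturbers = gm$perturbers, D = 1e-3,
                                         seed = 1)),
               "gridded")
  expect_error(run_simulation(sim_config("3D-CTN-CYL-ANA-MC", gm$spec, sq,
                                         perturbers = gm$perturbers, D = 1e-3,
                                         nspins = 10, seed = 1)),
               "3D|2D")
  expect_error(run_simulation(sim_config("2D-CTN-CYL-ANA-MC", gm$spec, sq,
                                         D = 1e-3, nspins = 10, seed = 1)),
               "perturber")
})

test_that("the custom-mask FFT pipeline runs end to end", {
  fx <- make_fixture("toy_mask_3d")
  sq <- build_sequence("GE", fx$config$te, fx$config$dt)
  sig <- run_simulation(sim_config("3D-GRD-VAN-FFT-MC", fx$spec, sq,
                                   voxel = fx$voxel, D = fx$config$D,
                                   nspins = 500, seed = 15))
  expect_equal(Mod(sig$total[1]), 500)
  n <- length(sig$time)
  expect_lt(Mod(sig$total[n]), 500)  # the magnetized sphere dephases spins
})

test_that("signal files round-trip with their metadata", {
  gm <- small_gm(seed = 16)
  sq <- build_sequence("SE", 0.01, 5e-4)
  sig <- run_simulation(sim_config("2D-CTN-CYL-ANA-MC", gm$spec, sq,
                                   perturbers = gm$perturbers, D = 1e-3,
                                   nspins = 100, seed = 17))
  f <- tempfile(fileext = ".csv")
  write_signal(sig, f)
  back <- read_signal(f)
  expect_equal(back$total, sig$total, tolerance = 1e-12)
  expect_identical(back$method, sig$method)
  expect_identical(back$seed, sig$seed)
  expect_identical(back$config_hash, sig$config_hash)
  unlink(f)
})
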