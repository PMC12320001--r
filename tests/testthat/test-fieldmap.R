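test_that("cylinder field matches the dipole closed forms", {
  B0 <- 3; dchi <- 1e-6
  # 3D, field along the axis: inside value B0 dchi / 6 * 2, outside 0
  cyl <- one_cylz3d(W = 0.1, R = 1e-3, dchi = dchi)
  inside <- c(0.05, 0.05, 0.02)
  expect_equal(cylinder_field_3d(inside, cyl, B0, c(0, 0, 1)), 1e-6,
               tolerance = 1e-12)
  expect_equal(cylinder_field_3d(c(0.052, 0.05, 0.07), cyl, B0, c(0, 0, 1)),
               0, tolerance = 1e-18)
  # perpendicular field, point at r = 2R along the field projection
  expect_equal(cylinder_field_3d(c(0.052, 0.05, 0.05), cyl, B0, c(1, 0, 0)),
               B0 * dchi / 2 * (1 / 4), tolerance = 1e-12)
  # magic angle: 3 cos^2(theta) - 1 = 0 kills the inside field
  ct <- sqrt(1 / 3)
  bmagic <- c(sqrt(1 - ct^2), 0, ct)
  expect_lt(abs(cylinder_field_3d(inside, cyl, B0, bmagic)),
            1e-12 * B0 * dchi)

  # 2D with per-cylinder effective orientation
  c2 <- one_cyl2d(W = 0.1, R = 1e-3, theta = pi / 2, phi0 = 0, dchi = dchi)
  expect_equal(cylinder_field_2d(c(0.052, 0.05), c2, B0), B0 * dchi / 8,
               tolerance = 1e-12)
  c0 <- one_cyl2d(W = 0.1, R = 1e-3, theta = 0, phi0 = 0, dchi = dchi)
  expect_identical(cylinder_field_2d(c(0.052, 0.05), c0, B0), 0)
})

test_that("2D and 3D cylinder fields agree at matched (r, theta, phi)", {
  B0 <- 3; dchi <- 1e-6; R <- 1e-3
  theta <- 1.1
  # 3D: axis along z, field tilted by theta in the x-z plane
  c3 <- one_cylz3d(W = 0.1, R = R, dchi = dchi)
  b <- c(sin(theta), 0, cos(theta))
  # 2D: same theta, field projection along +x (phi0 = 0)
  c2 <- one_cyl2d(W = 0.1, R = R, theta = theta, phi0 = 0, dchi = dchi)
  for (ang in c(0, 0.3, 1.2, 2.5)) {
    p2 <- c(0.05 + 2 * R * cos(ang), 0.05 + 2 * R * sin(ang))
    p3 <- c(p2, 0.07)
    expect_equal(cylinder_field_2d(p2, c2, B0),
                 cylinder_field_3d(p3, c3, B0, b), tolerance = 1e-12)
  }
})

test_that("sphere field matches the dipole closed form and is zero inside", {
  B0 <- 3; dchi <- 1e-6; R <- 1e-3
  sph <- one_sph3d(W = 0.1, R = R, dchi = dchi)
  expect_identical(sphere_field(c(0.05, 0.05, 0.0505), sph, B0), 0)
  expect_identical(sphere_field(rep(0.05, 3), sph, B0), 0)
  # on the field axis at r = R: B0 dchi / 3 * 2
  expect_equal(sphere_field(c(0.05, 0.05, 0.05 + R), sph, B0, c(0, 0, 1)),
               2e-6, tolerance = 1e-12)
  ct <- sqrt(1 / 3)
  pm <- c(0.05 + 2 * R * sqrt(1 - ct^2), 0.05, 0.05 + 2 * R * ct)
  expect_lt(abs(sphere_field(pm, sph, B0, c(0, 0, 1))), 1e-12 * B0 * dchi)
})

test_that("superposition is linear and decays with the dipole exponents", {
  B0 <- 3
  two <- cylinders_2d(1e-3, rbind(c(0.03, 0.05), c(0.07, 0.05)),
                      theta = pi / 2, phi0 = 0, dchi = 1e-6)
  left <- cylinders_2d(1e-3, c(0.03, 0.05), pi / 2, 0, 1e-6)
  right <- cylinders_2d(1e-3, c(0.07, 0.05), pi / 2, 0, 1e-6)
  mid <- c(0.05, 0.05)
  expect_equal(analytic_field(mid, two, B0),
               analytic_field(mid, left, B0) + analytic_field(mid, right, B0),
               tolerance = 1e-15)

  one <- one_cyl2d(W = 0.1, R = 1e-3, theta = pi / 2, phi0 = 0)
  f1 <- analytic_field(c(0.05 + 4e-3, 0.05), one, B0)
  f2 <- analytic_field(c(0.05 + 8e-3, 0.05), one, B0)
  expect_equal(f1 / f2, 4, tolerance = 1e-9)

  sph <- one_sph3d(R = 1e-3)
  g1 <- analytic_field(c(0.05, 0.05, 0.05 + 4e-3), sph, B0)
  g2 <- analytic_field(c(0.05, 0.05, 0.05 + 8e-3), sph, B0)
  expect_equal(g1 / g2, 8, tolerance = 1e-9)
})

test_that("the exterior dipole field has zero mean over a spherical shell", {
  set.seed(4)
  n <- 2e4
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  sph <- one_sph3d(W = 0.1, R = 1e-3)
  shell <- sweep(u * 5e-3, 2, rep(0.05, 3), "+")
  f <- analytic_field(shell, sph, 3)
  expect_lt(abs(mean(f)), 3 * sd(f) / sqrt(n))
  cyl <- one_cylz3d(W = 0.1, R = 1e-3)
  ang <- seq(0, 2 * pi, length.out = 3601)[-1]  # no duplicated endpoint
  ring <- cbind(0.05 + 5e-3 * cos(ang), 0.05 + 5e-3 * sin(ang), 0.05)
  fc <- analytic_field(ring, cyl, 3, c(1, 0, 0))
  expect_lt(abs(mean(fc)), 1e-9 * max(abs(fc)))
})

test_that("offsets are invariant under joint rotation of field and geometry", {
  B0 <- 3
  th <- 0.7; R3 <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
                         c(0, 0, 1))
  axis <- c(0.3, 0.5, sqrt(1 - 0.34)); axis <- axis / sqrt(sum(axis^2))
  ctr <- rep(0.05, 3)
  cyl <- cylinders_3d(1e-3, ctr, axis, 1e-6)
  b <- c(0, 0, 1)
  pts <- sweep(matrix(rnorm(30, 0, 3e-3), ncol = 3), 2, ctr, "+")
  f0 <- analytic_field(pts, cyl, B0, b)
  cyl_r <- cylinders_3d(1e-3, ctr, as.numeric(R3 %*% axis), 1e-6)
  pts_r <- t(R3 %*% (t(pts) - ctr) + ctr)
  f1 <- analytic_field(pts_r, cyl_r, B0, as.numeric(R3 %*% b))
  expect_equal(f0, f1, tolerance = 1e-10)
})

test_that("the spatial dipole kernel has the documented singular and axis values", {
  d <- 2
  K <- dipole_kernel_3d(9, spacing = 1)
  c0 <- 5  # index of zero offset
  expect_identical(K[c0, c0, c0], 0)
  expect_equal(K[c0, c0, c0 + d], (1 / (4 * pi)) * 2 / d^3, tolerance = 1e-12)
  expect_equal(K[c0 + d, c0, c0], -(1 / (4 * pi)) / d^3, tolerance = 1e-12)
})

test_that("FFT field of a uniform susceptibility map is constant in periodic mode", {
  N <- 16
  spec <- voxel_spec(3L, 0.1, "gridded", N = N)
  chi <- array(2e-6, dim = rep(N, 3))
  lab <- array(1L, dim = rep(N, 3))
  gv <- gridded_voxel(spec, lab, chi)
  fg <- fft_field(gv, pad = 0)
  expect_lt(diff(range(fg$values)), 1e-18 + 1e-9 * max(abs(fg$values)))
})

test_that("FFT field matches the analytic sphere field away from surfaces", {
  fx <- make_fixture("single_sphere_3d")
  gv <- discretize_voxel(fx$perturbers, fx$spec, subsample = 4)
  fg <- fft_field(gv)
  ana <- analytic_field_grid(fx$perturbers, fx$spec)
  N <- fx$spec$N; dx <- fx$spec$W / N; R <- fx$perturbers$radius
  ctr <- grid_centers(fx$spec)
  r <- sqrt(rowSums(sweep(ctr, 2, rep(fx$spec$W / 2, 3))^2))
  interior <- abs(r - R) > 2 * dx &
    apply(ctr, 1, function(p) min(p, fx$spec$W - p)) > 4 * dx
  aa <- as.vector(ana$values)[interior]
  ff <- as.vector(fg$values)[interior]
  scale <- max(abs(aa))
  sel <- abs(aa) > 0.1 * scale
  expect_lt(max(abs(ff[sel] - aa[sel]) / abs(aa[sel])), 0.05)
  expect_lt(max(abs(ff[!sel] - aa[!sel])), 0.05 * scale)
})

test_that("padding beyond the wrap-free width leaves the FFT field unchanged", {
  fx <- make_fixture("single_sphere_3d", overrides = list(N = 32L))
  gv <- discretize_voxel(fx$perturbers, fx$spec)
  f_full <- fft_field(gv, pad = 31)
  f_more <- fft_field(gv, pad = 36)
  expect_equal(f_full$values, f_more$values, tolerance = 1e-10)
})

test_that("fft_field rejects unsupported grids", {
  expect_error(fft_field(array(0, c(4, 4)), B0 = 3, spacing = 1e-3), "3D")
  expect_error(fft_field(array(0, c(4, 4, 5)), B0 = 3, spacing = 1e-3),
               "non-cubic")
})
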