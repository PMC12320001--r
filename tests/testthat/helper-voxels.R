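# small shared geometries, built in code at test time

# one cylinder through the voxel center, 2D
one_cyl2d <- function(W = 0.1, R = W / 10, theta = pi / 2, phi0 = 0,
                      dchi = 1e-6, perm = 0) {
  cylinders_2d(R, c(W / 2, W / 2), theta = theta, phi0 = phi0,
               dchi = dchi, perm = perm)
}

one_sph3d <- function(W = 0.1, R = W / 8, dchi = 1e-6, perm = 0) {
  spheres_3d(R, rep(W / 2, 3), dchi = dchi, perm = perm)
}

one_cylz3d <- function(W = 0.1, R = W / 8, dchi = 1e-6, perm = 0) {
  cylinders_3d(R, rep(W / 2, 3), c(0, 0, 1), dchi = dchi, perm = perm)
}

# a small grey-matter-like voxel for fast simulation tests (fewer vessels
# than the full fixture)
small_gm <- function(seed = 1, W = 0.05, N = 150L, perm = 0) {
  spec <- voxel_spec(2L, W, "continuous", B0 = 3)
  pert <- make_random_cylinders_2d(spec, 1e-3, 0.02, ppm_cgs_to_si(0.3),
                                   perm = perm, seed = seed)
  list(spec = spec,
       gspec = voxel_spec(2L, W, "gridded", N = N, B0 = 3),
       perturbers = pert)
}

zero_chi <- function(perturbers) {
  perturbers$dchi <- 0
  perturbers
}
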