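#' Self-contained test and example voxels
#'
#' Deterministic generators for the standard configurations used throughout
#' the package's examples and tests; every fixture is a pure function of
#' `(name, seed, overrides)`.
#'
#' * `gm_cylinders_2d` - a grey-matter-like 2D voxel: randomly oriented
#'   infinite cylinders of radius 1 um at CBV 0.02, blood susceptibility
#'   0.3 ppm (cgs), D = 0.001 mm^2/s, spin-echo TE = 70 ms. Voxel width
#'   0.1 mm (about 64 vessels), grid N = 400 when discretized (8 elements
#'   across a vessel diameter).
#' * `wm_axons_2d` - a toy white-matter bundle in a 0.04 mm voxel: a
#'   jittered-hexagonal packing of non-overlapping axon cross-sections with
#'   diameters in 0.4-3.5 um and myelin susceptibility -0.15 ppm (cgs) at a
#'   target axon volume fraction of 0.5, interspersed with 1% CBV blood
#'   vessels carrying random effective field orientations. The main field is
#'   at 90 degrees to the fibres (axon `theta = pi/2`).
#' * `single_cylinder_3d` / `single_sphere_3d` - one centered analytic
#'   perturber (R = W/8) with a gridded N = 64 spec, the oracle geometry for
#'   field-map validation.
#' * `toy_mask_3d` - a small (N = 16) custom label mask containing one
#'   spherical compartment, exercising the mask/FFT path.
#'
#' @param name fixture name.
#' @param seed integer seed.
#' @param overrides named list overriding fixture parameters (e.g. `W`, `N`,
#'   `cbv`, `radius`, `dchi_ppm_cgs`, `D`, `te`, `dt`, `B0`, `perm`,
#'   `avf` for the axon volume fraction).
#' @return A list with elements `perturbers` (or `voxel` for mask fixtures),
#'   `spec`, and `config` (recommended simulation parameters: `D`, `te`,
#'   `dt`, `sequence_kind`, `B0`).
#' @export
make_fixture <- function(name = c("gm_cylinders_2d", "wm_axons_2d",
                                  "single_cylinder_3d", "single_sphere_3d",
                                  "toy_mask_3d"),
                         seed = 1L, overrides = list()) {
  name <- match.arg(name)
  switch(name,
         gm_cylinders_2d = fixture_gm(seed, overrides),
         wm_axons_2d = fixture_wm(seed, overrides),
         single_cylinder_3d = fixture_single(seed, overrides, "cylinder"),
         single_sphere_3d = fixture_single(seed, overrides, "sphere"),
         toy_mask_3d = fixture_mask(seed, overrides))
}

fix_par <- function(defaults, overrides) {
  utils::modifyList(defaults, overrides)
}

fixture_gm <- function(seed, overrides) {
  p <- fix_par(list(W = 0.1, N = 400L, radius = 1e-3, cbv = 0.02,
                    dchi_ppm_cgs = 0.3, D = 1e-3, te = 0.07, dt = 2e-4,
                    B0 = 3, perm = 0), overrides)
  spec <- voxel_spec(2L, p$W, "continuous", B0 = p$B0)
  pert <- make_random_cylinders_2d(spec, p$radius, p$cbv,
                                   ppm_cgs_to_si(p$dchi_ppm_cgs), p$perm,
                                   seed = seed)
  list(name = "gm_cylinders_2d", perturbers = pert, spec = spec,
       gridded_spec = voxel_spec(2L, p$W, "gridded", N = p$N, B0 = p$B0),
       config = list(D = p$D, te = p$te, dt = p$dt, sequence_kind = "SE",
                     B0 = p$B0))
}

fixture_wm <- function(seed, overrides) {
  p <- fix_par(list(W = 0.04, diam_range = c(0.4e-3, 3.5e-3), avf = 0.5,
                    dchi_ppm_cgs = -0.15, vessel_cbv = 0.01,
                    vessel_radius = 1e-3, vessel_dchi_ppm_cgs = 0.3,
                    D = 1e-3, te = 0.07, dt = 2e-4, B0 = 3, perm = 0),
              overrides)
  set.seed(derive_seed(seed, "wm-axons"))
  rr <- p$diam_range / 2
  mean_r2 <- (rr[1]^2 + rr[1] * rr[2] + rr[2]^2) / 3  # E[r^2], uniform radii
  pitch <- sqrt(pi * mean_r2 / (p$avf * sqrt(3) / 2))
  # jittered hexagonal lattice of candidate sites covering the voxel
  nx <- ceiling(p$W / pitch) + 1L
  ny <- ceiling(p$W / (pitch * sqrt(3) / 2)) + 1L
  sites <- do.call(rbind, lapply(seq_len(ny), function(j) {
    x0 <- if (j %% 2 == 0) pitch / 2 else 0
    cbind(x0 + (seq_len(nx) - 1) * pitch, (j - 1) * pitch * sqrt(3) / 2)
  }))
  sites <- sites + matrix(rnorm(length(sites), 0, 0.1 * pitch), ncol = 2)
  keep <- sites[, 1] >= 0 & sites[, 1] < p$W & sites[, 2] >= 0 & sites[, 2] < p$W
  sites <- sites[keep, , drop = FALSE]
  sites <- sites[sample.int(nrow(sites)), , drop = FALSE]
  # hard circles: draw radii, reject draws overlapping already-placed axons
  radii <- numeric(0)
  placed <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(sites))) {
    gap <- if (nrow(placed)) {
      min(sqrt(rowSums(sweep(placed, 2, sites[i, ])^2)) - radii)
    } else Inf
    if (gap <= rr[1]) next
    r <- NA
    for (try in 1:20) {
      cand <- runif(1, rr[1], rr[2])
      if (cand < gap) { r <- cand; break }
    }
    if (is.na(r)) r <- min(gap * 0.95, rr[2])
    if (r < rr[1]) next
    placed <- rbind(placed, sites[i, ])
    radii <- c(radii, r)
  }
  # axons: parallel fibres, field at 90 degrees (theta = pi/2, common phi0)
  axons <- cylinders_2d(radii, placed, theta = pi / 2, phi0 = pi / 2,
                        dchi = ppm_cgs_to_si(p$dchi_ppm_cgs), perm = p$perm)
  spec <- voxel_spec(2L, p$W, "continuous", B0 = p$B0)
  vessels <- make_random_cylinders_2d(
    spec, p$vessel_radius, p$vessel_cbv,
    ppm_cgs_to_si(p$vessel_dchi_ppm_cgs), p$perm,
    seed = derive_seed(seed, "wm-vessels"))
  # vessels listed first so they win containment ties against axons
  both <- new_perturber_set(rbind(as.data.frame(unclass(vessels)),
                                  as.data.frame(unclass(axons))),
                            "cylinder2d")
  list(name = "wm_axons_2d", perturbers = both, axons = axons,
       vessels = vessels, spec = spec,
       config = list(D = p$D, te = p$te, dt = p$dt, sequence_kind = "SE",
                     B0 = p$B0))
}

fixture_single <- function(seed, overrides, shape) {
  p <- fix_par(list(W = 0.1, N = 64L, dchi_ppm_cgs = 0.3, B0 = 3,
                    D = 1e-3, te = 0.07, dt = 2e-4, perm = 0), overrides)
  spec <- voxel_spec(3L, p$W, "gridded", N = p$N, B0 = p$B0)
  ctr <- rep(p$W / 2, 3)
  R <- p$W / 8
  pert <- if (shape == "sphere") {
    spheres_3d(R, ctr, ppm_cgs_to_si(p$dchi_ppm_cgs), p$perm)
  } else {
    cylinders_3d(R, ctr, c(0, 0, 1), ppm_cgs_to_si(p$dchi_ppm_cgs), p$perm)
  }
  list(name = paste0("single_", shape, "_3d"), perturbers = pert,
       spec = spec,
       config = list(D = p$D, te = p$te, dt = p$dt, sequence_kind = "SE",
                     B0 = p$B0))
}

fixture_mask <- function(seed, overrides) {
  p <- fix_par(list(W = 0.05, N = 16L, dchi_ppm_cgs = 0.3, B0 = 3,
                    D = 1e-3, te = 0.02, dt = 2e-4), overrides)
  spec <- voxel_spec(3L, p$W, "gridded", N = p$N, B0 = p$B0)
  ctr <- grid_centers(spec)
  r2 <- rowSums(sweep(ctr, 2, rep(p$W / 2, 3))^2)
  lab <- array(as.integer(r2 <= (p$W / 4)^2), dim = rep(p$N, 3))
  dchi <- array(ppm_cgs_to_si(p$dchi_ppm_cgs) * (lab > 0), dim = rep(p$N, 3))
  gv <- gridded_voxel(spec, lab, dchi, perm = 1)
  list(name = "toy_mask_3d", voxel = gv, spec = spec,
       config = list(D = p$D, te = p$te, dt = p$dt, sequence_kind = "GE",
                     B0 = p$B0))
}
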