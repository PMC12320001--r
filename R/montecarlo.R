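#' Diffusion configuration
#'
#' @param D diffusion coefficient (mm^2/s); 0 disables motion.
#' @param dt time step (s).
#' @return A `diffusion_config` list; the per-axis step standard deviation
#'   `sqrt(2 * D * dt)` is precomputed in `$sigma`.
#' @export
diffusion_config <- function(D, dt) {
  stopifnot(D >= 0, dt > 0)
  structure(list(D = D, dt = dt, sigma = sqrt(2 * D * dt)),
            class = "diffusion_config")
}

# geometry accessors shared by the MC path: analytic perturber set or grid
geom_kind_code <- function(geom) {
  if (inherits(geom, "gridded_voxel")) 4L else .pert_kind_code[[pert_kind(geom)]]
}

geom_label <- function(points, geom) {
  if (inherits(geom, "gridded_voxel")) {
    label_points_grid_cpp(rbind(points), geom$label, geom$spec$N, geom$spec$W)
  } else {
    label_points(points, geom)
  }
}

#' Initialize a spin ensemble
#'
#' Spins carry continuous-space positions in `[0, W)^ndim`, unit longitudinal
#' magnetization (no transverse component until an excitation pulse), and
#' the label of the compartment containing them (0 = extravascular).
#'
#' @param n number of spins.
#' @param spec a [voxel_spec()].
#' @param geom geometry used for compartment labels: a `perturber_set` or
#'   [gridded_voxel()]; `NULL` for an empty voxel.
#' @param seed integer seed; initialization is a pure function of it.
#' @param placement `"uniform"` over the voxel, `"ev_only"` (rejection-sample
#'   outside all perturbers) or `"iv_only"` (inside; fails on an empty
#'   voxel).
#' @return A `spin_ensemble`: list with `pos` (n x ndim), `mxy` (complex),
#'   `mz`, `label`, and bookkeeping fields.
#' @export
init_spins <- function(n, spec, geom = NULL, seed = 1L,
                       placement = c("uniform", "ev_only", "iv_only")) {
  placement <- match.arg(placement)
  stopifnot(n >= 1)
  set.seed(seed)
  draw <- function(m) matrix(runif(m * spec$ndim, 0, spec$W), ncol = spec$ndim)
  lab_of <- function(p) if (is.null(geom)) integer(nrow(p)) else geom_label(p, geom)
  pos <- draw(n)
  lab <- lab_of(pos)
  if (placement != "uniform") {
    want_iv <- placement == "iv_only"
    keep <- if (want_iv) lab > 0L else lab == 0L
    tries <- 0L
    while (!all(keep)) {
      tries <- tries + 1L
      if (tries > 1000L)
        stop(sprintf("could not place spins with placement '%s' (zero %s volume?)",
                     placement, if (want_iv) "perturber" else "extravascular"))
      idx <- which(!keep)
      pos[idx, ] <- draw(length(idx))
      lab[idx] <- lab_of(pos[idx, , drop = FALSE])
      keep <- if (want_iv) lab > 0L else lab == 0L
    }
  }
  structure(list(pos = pos, mxy = complex(real = rep(0, n)),
                 mz = rep(1, n), label = lab, n = n, spec = spec,
                 n_stuck = 0L), class = "spin_ensemble")
}

#' One Monte Carlo diffusion step
#'
#' Each spin takes a step with per-axis displacements drawn from
#' `Normal(0, 2 D dt)`; positions wrap periodically on `[0, W)`. A step whose
#' endpoint lies in a different compartment than its start is a wall
#' crossing: permeation succeeds with the wall's permeation probability (one
#' Bernoulli draw per attempted crossing), otherwise new steps are drawn
#' until one stays in the starting compartment (up to `max_retry`, after
#' which the spin remains in place for this step; occurrences are counted in
#' `$n_stuck`). The raw accepted displacement (before wrapping) is returned
#' in attribute `"disp"` for mean-squared-displacement bookkeeping.
#'
#' @param ens a `spin_ensemble`.
#' @param cfg a [diffusion_config()].
#' @param geom a `perturber_set` or [gridded_voxel()] (may be `NULL` for free
#'   diffusion).
#' @param max_retry resample cap per spin and step.
#' @return The updated ensemble.
#' @export
mc_step <- function(ens, cfg, geom = NULL, max_retry = 100L) {
  if (cfg$sigma == 0) {
    attr(ens, "disp") <- matrix(0, ens$n, ens$spec$ndim)
    return(ens)
  }
  if (is.null(geom)) {
    step <- matrix(rnorm(ens$n * ens$spec$ndim, 0, cfg$sigma),
                   ncol = ens$spec$ndim)
    ens$pos <- (ens$pos + step) %% ens$spec$W
    attr(ens, "disp") <- step
    return(ens)
  }
  kind <- geom_kind_code(geom)
  if (kind == 4L) {
    res <- mc_step_cpp(ens$pos, ens$label, cfg$sigma, ens$spec$W, 4L,
                       matrix(numeric(0), 0, 0), as.vector(geom$label),
                       geom$spec$N, geom$perm, as.integer(max_retry))
  } else {
    res <- mc_step_cpp(ens$pos, ens$label, cfg$sigma, ens$spec$W, kind,
                       pert_matrix(geom), integer(0), 0L,
                       geom$perm, as.integer(max_retry))
  }
  ens$pos <- res$pos
  ens$label <- res$label
  ens$n_stuck <- ens$n_stuck + res$n_stuck
  attr(ens, "disp") <- res$disp
  ens
}

#' Field offset at the spin positions
#'
#' Continuous field sources (a `perturber_set` plus field parameters) give
#' the exact analytic superposition at each position; gridded sources (a
#' `field_grid`) give the value of the grid element containing the position.
#'
#' @param ens a `spin_ensemble`.
#' @param field_source a `perturber_set` or a `field_grid`.
#' @param B0,B0_dir field parameters for the analytic source.
#' @return Numeric vector of per-spin dBz (T).
#' @export
sample_field <- function(ens, field_source, B0 = NULL, B0_dir = c(0, 0, 1)) {
  if (inherits(field_source, "field_grid")) {
    spec <- field_source$spec
    dx <- grid_dx(spec)
    idx <- pmin(pmax(floor(ens$pos / dx), 0), spec$N - 1)
    lin <- as.integer(idx %*% spec$N^(seq_len(spec$ndim) - 1)) + 1L
    as.vector(field_source$values)[lin]
  } else {
    if (is.null(B0)) stop("B0 is required for an analytic field source")
    analytic_field(ens$pos, field_source, B0, B0_dir)
  }
}
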