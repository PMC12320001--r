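#' Define the simulation voxel
#'
#' A voxel is the simulation domain: a square (2D) or cube (3D) of width `W`
#' millimetres, spanning `[0, W)` along each axis, placed in a main field
#' `B0`. Gridded voxels are additionally discretized into `N` elements per
#' side, with element centers at `(i + 1/2) * W / N` (0-based `i`), the
#' convention used consistently by the discretizer, the FFT field path and
#' the periodic diffusion wrap.
#'
#' @param ndim 2 or 3.
#' @param W voxel width (mm).
#' @param representation `"continuous"` or `"gridded"`.
#' @param N grid elements per side (gridded only, `N >= 2`).
#' @param B0 main field strength (T).
#' @param B0_dir unit 3-vector giving the field direction (3D; in 2D each
#'   cylinder carries its own effective field orientation instead).
#' @return An object of class `voxel_spec`.
#' @export
voxel_spec <- function(ndim, W, representation = c("continuous", "gridded"),
                       N = NULL, B0 = 3, B0_dir = c(0, 0, 1)) {
  representation <- match.arg(representation)
  stopifnot(ndim %in% c(2L, 3L), is.numeric(W), length(W) == 1L, W > 0,
            is.numeric(B0), B0 >= 0)
  if (representation == "gridded") {
    if (is.null(N) || N < 2) stop("gridded voxels need N >= 2 grid elements per side")
    N <- as.integer(N)
  } else {
    N <- NULL
  }
  B0_dir <- as.numeric(B0_dir)
  stopifnot(length(B0_dir) == 3L)
  nb <- sqrt(sum(B0_dir^2))
  if (abs(nb - 1) > 1e-6) stop("B0_dir must be a unit vector")
  B0_dir <- B0_dir / nb
  structure(list(ndim = as.integer(ndim), W = W,
                 representation = representation, N = N,
                 B0 = B0, B0_dir = B0_dir),
            class = "voxel_spec")
}

#' @export
print.voxel_spec <- function(x, ...) {
  cat(sprintf("voxel_spec: %dD %s, W = %g mm%s, B0 = %g T\n",
              x$ndim, x$representation, x$W,
              if (!is.null(x$N)) sprintf(", N = %d (dx = %g mm)", x$N, x$W / x$N) else "",
              x$B0))
  invisible(x)
}

# grid spacing (mm)
grid_dx <- function(spec) spec$W / spec$N

# matrix of grid-element centers, one row per element, in R column-major
# order of the label/dchi arrays (first axis fastest)
grid_centers <- function(spec) {
  dx <- grid_dx(spec)
  ax <- (seq_len(spec$N) - 0.5) * dx
  if (spec$ndim == 2L) {
    cbind(rep(ax, times = spec$N), rep(ax, each = spec$N))
  } else {
    cbind(rep(ax, times = spec$N^2),
          rep(rep(ax, each = spec$N), times = spec$N),
          rep(ax, each = spec$N^2))
  }
}

# ---- perturber sets ---------------------------------------------------------

# canonical column orders shared with src/sim_core.cpp
.pert_cols <- list(
  cylinder2d = c("radius", "cx", "cy", "theta", "phi0", "dchi", "perm"),
  cylinder3d = c("radius", "px", "py", "pz", "dx", "dy", "dz", "dchi", "perm"),
  sphere3d   = c("radius", "cx", "cy", "cz", "dchi", "perm")
)
.pert_kind_code <- c(cylinder2d = 1L, cylinder3d = 2L, sphere3d = 3L)

new_perturber_set <- function(df, kind) {
  stopifnot(kind %in% names(.pert_cols), all(.pert_cols[[kind]] %in% names(df)))
  df <- df[, .pert_cols[[kind]], drop = FALSE]
  if (nrow(df)) {
    stopifnot(all(df$radius > 0), all(df$perm >= 0 & df$perm <= 1))
  }
  structure(df, class = c(paste0(kind, "_set"), "perturber_set", "data.frame"),
            kind = kind, ndim = if (kind == "cylinder2d") 2L else 3L)
}

pert_kind <- function(p) attr(p, "kind")
pert_matrix <- function(p) {
  m <- as.matrix(as.data.frame(unclass(p))[, .pert_cols[[pert_kind(p)]]])
  storage.mode(m) <- "double"
  m
}

#' Perturber constructors
#'
#' Build sets of analytic susceptibility perturbers. 2D cylinders are always
#' perpendicular to the voxel plane and instead carry their own effective
#' field orientation: `theta` is the angle between the main field and the
#' cylinder axis and `phi0` the in-plane azimuth of the field projection.
#' 3D cylinders are infinite along `axis_dir`; containment and field use the
#' perpendicular distance only. Spheres have no orientation.
#'
#' @param radius perturber radius (mm), recycled.
#' @param center n x 2 (2D) or n x 3 (spheres) matrix of centers (mm).
#' @param theta,phi0 per-cylinder effective field angles (rad), 2D only.
#' @param axis_point,axis_dir n x 3 matrices: a point on each 3D cylinder
#'   axis and its (unit) direction.
#' @param dchi dimensionless SI susceptibility difference
#'   (see [ppm_cgs_to_si()]).
#' @param perm water permeation probability per wall crossing, in `[0, 1]`.
#' @return A `perturber_set` data frame.
#' @name perturbers
NULL

#' @rdname perturbers
#' @export
cylinders_2d <- function(radius, center, theta, phi0 = 0, dchi, perm = 0) {
  center <- rbind(center)
  n <- nrow(center)
  stopifnot(ncol(center) == 2L, all(theta >= 0 & theta <= pi))
  new_perturber_set(data.frame(
    radius = rep_len(radius, n), cx = center[, 1], cy = center[, 2],
    theta = rep_len(theta, n), phi0 = rep_len(phi0, n),
    dchi = rep_len(dchi, n), perm = rep_len(perm, n)), "cylinder2d")
}

#' @rdname perturbers
#' @export
cylinders_3d <- function(radius, axis_point, axis_dir, dchi, perm = 0) {
  axis_point <- rbind(axis_point); axis_dir <- rbind(axis_dir)
  n <- nrow(axis_point)
  stopifnot(ncol(axis_point) == 3L, ncol(axis_dir) == 3L, nrow(axis_dir) == n)
  nrm <- sqrt(rowSums(axis_dir^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("axis_dir rows must be unit vectors")
  axis_dir <- axis_dir / nrm
  new_perturber_set(data.frame(
    radius = rep_len(radius, n),
    px = axis_point[, 1], py = axis_point[, 2], pz = axis_point[, 3],
    dx = axis_dir[, 1], dy = axis_dir[, 2], dz = axis_dir[, 3],
    dchi = rep_len(dchi, n), perm = rep_len(perm, n)), "cylinder3d")
}

#' @rdname perturbers
#' @export
spheres_3d <- function(radius, center, dchi, perm = 0) {
  center <- rbind(center)
  n <- nrow(center)
  stopifnot(ncol(center) == 3L)
  new_perturber_set(data.frame(
    radius = rep_len(radius, n),
    cx = center[, 1], cy = center[, 2], cz = center[, 3],
    dchi = rep_len(dchi, n), perm = rep_len(perm, n)), "sphere3d")
}

# empty set of a given kind
empty_perturbers <- function(kind) {
  cols <- .pert_cols[[kind]]
  df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  new_perturber_set(df, kind)
}

#' Containment labels for points
#'
#' Label each point by the first perturber containing it (1-based id), or 0
#' for the extra-perturber space.
#'
#' @param points n x ndim matrix of positions (mm).
#' @param perturbers a `perturber_set`.
#' @return Integer vector of labels.
#' @export
label_points <- function(points, perturbers) {
  points <- rbind(points)
  if (nrow(perturbers) == 0L) return(integer(nrow(points)))
  label_points_cpp(points, pert_matrix(perturbers),
                   .pert_kind_code[[pert_kind(perturbers)]])
}

# ---- random generation at a target CBV --------------------------------------

# shared incremental generator: keeps adding perturbers (drawn by draw_fn)
# until the Monte-Carlo-estimated occupied fraction over a fixed point cloud
# first reaches target_cbv
generate_to_cbv <- function(spec, target_cbv, draw_fn, covers_fn, rbind_fn,
                            tol, max_perturbers, n_est) {
  pts <- matrix(runif(n_est * spec$ndim, 0, spec$W), ncol = spec$ndim)
  covered <- rep(FALSE, n_est)
  rows <- list()
  est <- 0
  while (est < target_cbv) {
    if (length(rows) >= max_perturbers)
      stop(sprintf("target CBV %g not reached within the cap of %g perturbers",
                   target_cbv, max_perturbers))
    p <- draw_fn()
    prev_covered <- covered
    covered <- covered | covers_fn(p, pts)
    rows[[length(rows) + 1L]] <- p
    est <- mean(covered)
  }
  # keep whichever of (with, without) the final perturber lands closer
  if (length(rows) > 1L &&
      abs(mean(prev_covered) - target_cbv) < abs(est - target_cbv)) {
    rows <- rows[-length(rows)]
    covered <- prev_covered
    est <- mean(covered)
  }
  if (abs(est - target_cbv) > tol * target_cbv)
    stop(sprintf(paste0("generated CBV %.4g misses target %.4g by more than ",
                        "the relative tolerance %g (perturber increments too ",
                        "coarse); use smaller radii or a wider voxel"),
                 est, target_cbv, tol))
  res <- rbind_fn(rows)
  attr(res, "cbv_est") <- est
  res
}

#' Random perturber generation at a target volume fraction
#'
#' Perturbers are added one at a time, each drawn independently, until the
#' Monte-Carlo-estimated union volume (area) fraction over a fixed cloud of
#' `n_est` uniform sample points first reaches `target_cbv`; the final
#' estimate must lie within `tol` (relative) of the target. 3D cylinder axes
#' are uniformly distributed on the sphere and pass through a uniform random
#' point in the sphere of radius `W * sqrt(3) / 2` enclosing the voxel, which
#' yields a uniformly distributed CBV across the voxel. 2D cylinders get
#' centers uniform in the square and effective field orientations with
#' `cos(theta)` uniform on `[-1, 1]` (the angle distribution between a fixed
#' field and uniformly random 3D axes) and `phi0` uniform on `[0, 2*pi)`.
#' Sphere centers are uniform in the cube. Overlap between perturbers is
#' allowed; the CBV is the fraction of the union.
#'
#' @param spec a [voxel_spec()] of matching dimensionality.
#' @param radius perturber radius (mm).
#' @param target_cbv target volume/area fraction in `[0, 1)`.
#' @param dchi SI susceptibility difference assigned to every perturber.
#' @param perm permeation probability assigned to every perturber.
#' @param seed integer seed; generation is a pure function of it.
#' @param tol relative tolerance on the achieved CBV (default 10%).
#' @param max_perturbers cap on the number of perturbers.
#' @param n_est number of Monte Carlo sample points for the running CBV
#'   estimate.
#' @return A `perturber_set`; the achieved estimate is in attribute
#'   `"cbv_est"`.
#' @name random_perturbers
NULL

#' @rdname random_perturbers
#' @export
make_random_cylinders_3d <- function(spec, radius, target_cbv, dchi, perm = 0,
                                     seed = 1L, tol = 0.1,
                                     max_perturbers = 1e5, n_est = 1e5) {
  stopifnot(spec$ndim == 3L, target_cbv >= 0, target_cbv < 1)
  if (target_cbv == 0) return(empty_perturbers("cylinder3d"))
  set.seed(seed)
  ctr <- rep(spec$W / 2, 3)
  Renc <- spec$W * sqrt(3) / 2
  draw_fn <- function() {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    p <- ctr + Renc * runif(1)^(1 / 3) * u
    # snap the sampled point onto the axis: the axis passes through p
    c(p, a)
  }
  covers_fn <- function(par, pts) {
    u <- sweep(pts, 2, par[1:3])
    proj <- drop(u %*% par[4:6])
    rowSums((u - outer(proj, par[4:6]))^2) <= radius^2
  }
  rows <- generate_to_cbv(spec, target_cbv, draw_fn, covers_fn,
                          function(r) do.call(rbind, r), tol,
                          max_perturbers, n_est)
  out <- cylinders_3d(radius, rows[, 1:3, drop = FALSE],
                      rows[, 4:6, drop = FALSE], dchi, perm)
  attr(out, "cbv_est") <- attr(rows, "cbv_est")
  out
}

#' @rdname random_perturbers
#' @export
make_random_cylinders_2d <- function(spec, radius, target_cbv, dchi, perm = 0,
                                     seed = 1L, tol = 0.1,
                                     max_perturbers = 1e5, n_est = 1e5) {
  stopifnot(spec$ndim == 2L, target_cbv >= 0, target_cbv < 1)
  if (target_cbv == 0) return(empty_perturbers("cylinder2d"))
  set.seed(seed)
  draw_fn <- function() {
    c(runif(2, 0, spec$W), acos(runif(1, -1, 1)), runif(1, 0, 2 * pi))
  }
  covers_fn <- function(par, pts) {
    (pts[, 1] - par[1])^2 + (pts[, 2] - par[2])^2 <= radius^2
  }
  rows <- generate_to_cbv(spec, target_cbv, draw_fn, covers_fn,
                          function(r) do.call(rbind, r), tol,
                          max_perturbers, n_est)
  out <- cylinders_2d(radius, rows[, 1:2, drop = FALSE], rows[, 3], rows[, 4],
                      dchi, perm)
  attr(out, "cbv_est") <- attr(rows, "cbv_est")
  out
}

#' @rdname random_perturbers
#' @export
make_random_spheres_3d <- function(spec, radius, target_cbv, dchi, perm = 0,
                                   seed = 1L, tol = 0.1,
                                   max_perturbers = 1e5, n_est = 1e5) {
  stopifnot(spec$ndim == 3L, target_cbv >= 0, target_cbv < 1)
  if (target_cbv == 0) return(empty_perturbers("sphere3d"))
  set.seed(seed)
  draw_fn <- function() runif(3, 0, spec$W)
  covers_fn <- function(par, pts) {
    (pts[, 1] - par[1])^2 + (pts[, 2] - par[2])^2 +
      (pts[, 3] - par[3])^2 <= radius^2
  }
  rows <- generate_to_cbv(spec, target_cbv, draw_fn, covers_fn,
                          function(r) do.call(rbind, r), tol,
                          max_perturbers, n_est)
  out <- spheres_3d(radius, rows, dchi, perm)
  attr(out, "cbv_est") <- attr(rows, "cbv_est")
  out
}

#' Monte Carlo estimate of the perturber volume fraction
#'
#' Estimates the union volume (3D) or area (2D) fraction of the voxel
#' occupied by the perturbers, by uniform rejection sampling. Overlapping
#' perturbers count once (union semantics).
#'
#' @inheritParams random_perturbers
#' @param perturbers a `perturber_set`.
#' @param n_samples number of uniform sample points (>= 1e4).
#' @return The estimated fraction, with the binomial standard error in
#'   attribute `"se"`.
#' @export
compute_cbv <- function(perturbers, spec, n_samples = 1e5, seed = 1L) {
  stopifnot(n_samples >= 1e4)
  if (nrow(perturbers) == 0L) {
    return(structure(0, se = 0))
  }
  set.seed(seed)
  pts <- matrix(runif(n_samples * spec$ndim, 0, spec$W), ncol = spec$ndim)
  inside <- label_points(pts, perturbers) > 0L
  est <- mean(inside)
  structure(est, se = sqrt(est * (1 - est) / n_samples))
}

# ---- discretization ---------------------------------------------------------

#' Construct a gridded voxel directly from arrays
#'
#' Used for custom (externally generated) perturber masks: a label grid with
#' 0 marking the extra-perturber space and positive integers marking
#' perturber compartments, plus a susceptibility map and optional relaxation
#' maps.
#'
#' @param spec a gridded [voxel_spec()].
#' @param label integer array, `N^ndim`.
#' @param dchi numeric array of SI susceptibility per element (same shape);
#'   must be 0 wherever `label` is 0 unless `allow_background_chi = TRUE`.
#' @param t2,t1 optional per-element relaxation time arrays (s).
#' @param perm optional permeation probability per perturber id.
#' @param allow_background_chi allow nonzero susceptibility outside labelled
#'   elements (custom masks may specify this deliberately).
#' @return An object of class `gridded_voxel`.
#' @export
gridded_voxel <- function(spec, label, dchi, t2 = NULL, t1 = NULL,
                          perm = NULL, allow_background_chi = FALSE) {
  stopifnot(inherits(spec, "voxel_spec"), spec$representation == "gridded")
  shape <- rep(spec$N, spec$ndim)
  for (nm in c("label", "dchi", "t2", "t1")) {
    g <- get(nm)
    if (!is.null(g) && !identical(dim(g), as.integer(shape)))
      stop(sprintf("grid '%s' does not have shape %s", nm,
                   paste(shape, collapse = "x")))
  }
  if (!allow_background_chi && any(dchi[label == 0L] != 0))
    stop("dchi must be 0 where label is 0 (set allow_background_chi = TRUE for custom masks)")
  storage.mode(label) <- "integer"
  nlab <- max(0L, label)
  if (is.null(perm)) perm <- rep(0, nlab)
  if (length(perm) < nlab) perm <- rep_len(perm, nlab)
  structure(list(spec = spec, label = label, dchi = dchi,
                 t2 = t2, t1 = t1, perm = as.numeric(perm)),
            class = "gridded_voxel")
}

#' @export
print.gridded_voxel <- function(x, ...) {
  cat(sprintf("gridded_voxel: %dD, N = %d, W = %g mm, %d labelled of %d elements\n",
              x$spec$ndim, x$spec$N, x$spec$W,
              sum(x$label > 0L), length(x$label)))
  invisible(x)
}

#' Discretize analytic perturbers onto the voxel grid
#'
#' Each grid-element center (at `(i + 1/2) * W / N`) is tested for
#' containment in each perturber; the first containing perturber provides the
#' element's label. With `subsample = 1` the susceptibility map is the
#' labelled perturber's value per element (binary voxelization). With
#' `subsample = s > 1` each element's susceptibility is averaged over
#' `s^ndim` uniformly spaced subpoints, a partial-volume map that removes
#' most of the jagged-boundary error from Fourier field calculations while
#' the labels (used for compartment assignment and wall detection) remain
#' center-based. Sampling adequacy is checked with [check_sampling()] and
#' under-resolved perturbers trigger a warning.
#'
#' @inheritParams compute_cbv
#' @param subsample subpoints per axis per element for the susceptibility
#'   map (1 = binary center containment).
#' @return A [gridded_voxel()] whose `perm` carries the per-perturber
#'   permeation probabilities.
#' @export
discretize_voxel <- function(perturbers, spec, subsample = 1L) {
  stopifnot(spec$representation == "gridded", subsample >= 1L)
  msgs <- check_sampling(spec, perturbers)
  for (m in msgs) warning(m, call. = FALSE)
  ctr <- grid_centers(spec)
  lab <- label_points(ctr, perturbers)
  shape <- rep(spec$N, spec$ndim)
  lab <- array(lab, dim = shape)
  dchi_vals <- c(0, perturbers$dchi)
  if (subsample == 1L) {
    dchi <- array(dchi_vals[lab + 1L], dim = shape)
  } else {
    dx <- grid_dx(spec)
    off1 <- ((seq_len(subsample) - 0.5) / subsample - 0.5) * dx
    offs <- as.matrix(do.call(expand.grid, rep(list(off1), spec$ndim)))
    acc <- numeric(nrow(ctr))
    for (k in seq_len(nrow(offs))) {
      sub_lab <- label_points(sweep(ctr, 2, offs[k, ], "+"), perturbers)
      acc <- acc + dchi_vals[sub_lab + 1L]
    }
    dchi <- array(acc / nrow(offs), dim = shape)
  }
  if (nrow(perturbers) > 0 && !any(lab > 0L))
    warning("no grid element falls inside any perturber; the grid undersamples the geometry",
            call. = FALSE)
  gridded_voxel(spec, lab, dchi, perm = perturbers$perm,
                allow_background_chi = subsample > 1L)
}

#' Check grid sampling of the perturbers
#'
#' Accurate discrete representation requires the smallest perturber to span
#' at least 6 grid elements across its diameter. Returns one message per
#' under-resolved perturber radius (empty for continuous voxels).
#'
#' @inheritParams compute_cbv
#' @return Character vector of warning messages (possibly empty).
#' @export
check_sampling <- function(spec, perturbers) {
  if (spec$representation != "gridded" || nrow(perturbers) == 0L)
    return(character(0))
  dx <- grid_dx(spec)
  bad <- sort(unique(perturbers$radius[2 * perturbers$radius < 6 * dx]))
  vapply(bad, function(r) {
    sprintf(paste0("perturber radius %g mm spans only %.1f grid elements ",
                   "across its diameter; at least 6 are recommended ",
                   "(grid spacing %g mm)"), r, 2 * r / dx, dx)
  }, character(1))
}
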