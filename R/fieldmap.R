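#' Analytic dipole field of single perturbers
#'
#' Closed-form field offset along the main field, `dBz`, of a single
#' susceptibility perturber at given points. For an infinite cylinder the
#' offset is `B0 * dchi / 6 * (3 cos^2(theta) - 1)` inside and
#' `B0 * dchi / 2 * (R / r)^2 * cos(2 phi) * sin^2(theta)` outside, with
#' `theta` the angle between the field and the cylinder axis, `r` the
#' perpendicular distance from the axis and `phi` the angle between the
#' perpendicular vector and the projection of the field onto the plane
#' orthogonal to the axis. For a sphere the offset is 0 inside and
#' `B0 * dchi / 3 * (R / r)^3 * (3 cos^2(theta) - 1)` outside, with `theta`
#' the angle between the field and the center-to-point vector. Both terms
#' vanish at the magic angle, `3 cos^2(theta) = 1`.
#'
#' @param points n x ndim matrix of positions (mm); a single point may be
#'   given as a vector.
#' @param cyl,sph a one-row `perturber_set` of the matching class.
#' @param B0 field strength (T).
#' @param B0_dir unit field direction (3D).
#' @return Numeric vector of field offsets (T).
#' @name single_fields
NULL

#' @rdname single_fields
#' @export
cylinder_field_3d <- function(points, cyl, B0, B0_dir = c(0, 0, 1)) {
  analytic_field(points, cyl, B0, B0_dir)
}

#' @rdname single_fields
#' @export
cylinder_field_2d <- function(points, cyl, B0) {
  analytic_field(points, cyl, B0)
}

#' @rdname single_fields
#' @export
sphere_field <- function(points, sph, B0, B0_dir = c(0, 0, 1)) {
  analytic_field(points, sph, B0, B0_dir)
}

#' Analytic field offset by superposition
#'
#' Sum of the single-perturber dipole offsets at each point. For a point
#' inside perturber k, the contribution of k uses its inside expression and
#' all other perturbers their outside expression (exact superposition,
#' linear in the susceptibilities).
#'
#' @inheritParams single_fields
#' @param perturbers a `perturber_set` (any number of rows).
#' @return Numeric vector of field offsets (T).
#' @export
analytic_field <- function(points, perturbers, B0, B0_dir = c(0, 0, 1)) {
  points <- rbind(points)
  stopifnot(ncol(points) == attr(perturbers, "ndim"))
  if (nrow(perturbers) == 0L) return(numeric(nrow(points)))
  b <- B0_dir / sqrt(sum(B0_dir^2))
  field_points_cpp(points, pert_matrix(perturbers),
                   .pert_kind_code[[pert_kind(perturbers)]], B0, b)
}

#' Spatial-domain 3D dipole kernel
#'
#' The unit dipole response `G(r) = (3 (r . b)^2 - r^2) / (4 pi r^5)`
#' sampled at element-center offsets `(k - floor(n/2)) * spacing` along each
#' axis, with the singular element at `r = 0` set to zero.
#'
#' @param n kernel width in elements per axis (kernel is `n^3`).
#' @param spacing grid spacing (mm).
#' @param B0_dir unit field direction.
#' @return A `n x n x n` array.
#' @export
dipole_kernel_3d <- function(n, spacing, B0_dir = c(0, 0, 1)) {
  off <- (seq_len(n) - 1 - floor(n / 2)) * spacing
  dipole_kernel_at(off, off, off, B0_dir)
}

# dipole kernel evaluated at arbitrary per-axis offsets (r = 0 zeroed)
dipole_kernel_at <- function(offx, offy, offz, B0_dir) {
  b <- B0_dir / sqrt(sum(B0_dir^2))
  nx <- length(offx); ny <- length(offy); nz <- length(offz)
  X <- array(rep(offx, times = ny * nz), dim = c(nx, ny, nz))
  Y <- array(rep(rep(offy, each = nx), times = nz), dim = c(nx, ny, nz))
  Z <- array(rep(offz, each = nx * ny), dim = c(nx, ny, nz))
  r2 <- X^2 + Y^2 + Z^2
  rb <- X * b[1] + Y * b[2] + Z * b[3]
  G <- (3 * rb^2 - r2) / (4 * pi * r2^2.5)
  G[r2 == 0] <- 0
  G
}

#' Field offset by Fourier convolution with the dipole kernel
#'
#' Computes `dBz = IFFT(FFT(chi) . FFT(G)) * B0` on a zero-padded domain and
#' crops back to the voxel. The kernel is evaluated in the spatial domain
#' (same size as the voxel, `M = N` per axis) and no analytic value replaces
#' its zero-frequency component. With `pad = "full"` each axis is padded by
#' `M - 1` zeros, the amount that prevents wrap-around of an `N`-wide
#' susceptibility map convolved with an `M`-wide kernel. `pad = 0` gives the
#' periodic-surround behaviour in which the voxel is effectively tiled by
#' copies of itself; along such axes the kernel is summed over the periodic
#' images so that the circular convolution sees the full (untruncated)
#' dipole response of the tiled sources. Per-axis values may mix the two
#' (e.g. periodic along a cylinder axis, padded across it, which makes the
#' finite grid an exactly infinite cylinder). Only 3D grids are supported; the 2D
#' cylinder representation assigns each cylinder its own effective field
#' direction, which no single convolution kernel can express.
#'
#' @param x a [gridded_voxel()] (its `dchi` map is convolved) or a 3D
#'   susceptibility array.
#' @param B0,B0_dir field strength (T) and unit direction; defaults are taken
#'   from the voxel spec when `x` is a `gridded_voxel`.
#' @param spacing grid spacing (mm), required when `x` is a bare array.
#' @param pad `"full"`, or a non-negative integer (scalar or per-axis) number
#'   of zero-padding elements added to each axis.
#' @return A `field_grid`: list with `values` (array of dBz, T) and `spec`.
#' @export
fft_field <- function(x, B0 = NULL, B0_dir = NULL, spacing = NULL,
                      pad = "full") {
  if (inherits(x, "gridded_voxel")) {
    spec <- x$spec
    chi <- x$dchi
    if (is.null(B0)) B0 <- spec$B0
    if (is.null(B0_dir)) B0_dir <- spec$B0_dir
    spacing <- grid_dx(spec)
  } else {
    chi <- x
    spec <- NULL
    if (is.null(B0) || is.null(spacing))
      stop("B0 and spacing are required for a bare susceptibility array")
    if (is.null(B0_dir)) B0_dir <- c(0, 0, 1)
  }
  dims <- dim(chi)
  if (length(dims) != 3L)
    stop("fft_field requires a 3D grid (the dipole kernel is 3D)")
  if (length(unique(dims)) != 1L)
    stop("non-cubic grids are not supported")
  N <- dims[1]
  M <- N  # kernel support equals the voxel size
  if (identical(pad, "full")) pad <- rep(M - 1L, 3L)
  pad <- rep_len(as.integer(pad), 3L)
  stopifnot(all(pad >= 0))
  S <- dims + pad

  chi_pad <- array(0, dim = S)
  chi_pad[seq_len(N), seq_len(N), seq_len(N)] <- chi

  # along axes with no padding the convolution is circular, so the source is
  # effectively tiled periodically; the consistent kernel is the dipole
  # kernel summed over the corresponding periodic images (the untruncated
  # tail of an infinite cylinder's field, for instance, lives here)
  periodic <- pad == 0L
  n_per <- sum(periodic)
  P <- if (n_per == 0L) 0L else c(16L, 10L, 4L)[n_per]
  off_el <- seq_len(M) - 1 - floor(M / 2)
  images <- lapply(seq_len(3), function(a) if (periodic[a]) -P:P else 0L)
  G <- array(0, dim = rep(M, 3))
  for (m1 in images[[1]]) for (m2 in images[[2]]) for (m3 in images[[3]]) {
    G <- G + dipole_kernel_at((off_el + m1 * S[1]) * spacing,
                              (off_el + m2 * S[2]) * spacing,
                              (off_el + m3 * S[3]) * spacing, B0_dir)
  }
  off <- off_el
  G_pad <- array(0, dim = S)
  ix <- (off %% S[1]) + 1L
  iy <- (off %% S[2]) + 1L
  iz <- (off %% S[3]) + 1L
  G_pad[ix, iy, iz] <- G

  conv <- stats::fft(stats::fft(chi_pad) * stats::fft(G_pad), inverse = TRUE) /
    prod(S)
  vals <- Re(conv[seq_len(N), seq_len(N), seq_len(N)]) * B0 * spacing^3
  structure(list(values = vals, spec = spec), class = "field_grid")
}

#' Analytic field sampled on the voxel grid
#'
#' Evaluates the exact superposition field at every grid-element center,
#' the gridded counterpart of [analytic_field()] used by the GRD-ANA method
#' family.
#'
#' @inheritParams compute_cbv
#' @return A `field_grid`.
#' @export
analytic_field_grid <- function(perturbers, spec) {
  stopifnot(spec$representation == "gridded")
  vals <- analytic_field(grid_centers(spec), perturbers, spec$B0, spec$B0_dir)
  structure(list(values = array(vals, dim = rep(spec$N, spec$ndim)),
                 spec = spec), class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("field_grid: %s elements, dBz in [%.3g, %.3g] T\n",
              paste(dim(x$values), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}
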