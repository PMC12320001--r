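#' Diffusion kernels for the deterministic backend
#'
#' One diffusion step smooths the magnetization grid with a discrete kernel
#' whose width is the per-axis diffusion length `sigma = sqrt(2 D dt)`. The
#' Gaussian kernel samples `exp(-x^2 / (2 sigma^2))` at offsets `k * dx`,
#' `k in [-n_hw, n_hw]`; the Bessel kernel is the lattice-exact analogue
#' built from the modified Bessel function of the first kind,
#' `D_k = exp(-t) I_{k - n_hw}(t)` with `t = (sigma / dx)^2`, whose
#' untruncated sum over all integer orders is exactly 1. Both kernels are
#' renormalized to unit sum after truncation so that convolution conserves
#' total magnetization. A kernel that keeps fewer than about 5 meaningful
#' elements no longer represents the diffusion distribution (the
#' under-resolution hazard of holding the grid-element count fixed while the
#' voxel grows); a warning is issued when the truncated tail mass exceeds
#' 1e-3 before renormalization.
#'
#' @param sigma diffusion length per step (mm), `sqrt(2 D dt)`.
#' @param dx grid spacing (mm).
#' @param n_hw half-width in elements; the kernel has `2 n_hw + 1` weights.
#'   Default spans at least 3.5 sigma (minimum 5, giving 11 elements).
#' @return A `diffusion_kernel`: list with `weights`, `sigma`, `dx`, `kind`.
#' @name diffusion_kernels
NULL

new_kernel <- function(w, sigma, dx, kind) {
  w <- w / sum(w)
  structure(list(weights = w, sigma = sigma, dx = dx, kind = kind,
                 n_hw = (length(w) - 1L) %/% 2L),
            class = "diffusion_kernel")
}

default_n_hw <- function(sigma, dx) max(5L, as.integer(ceiling(3.5 * sigma / dx)))

#' @rdname diffusion_kernels
#' @export
gaussian_kernel <- function(sigma, dx, n_hw = default_n_hw(sigma, dx)) {
  stopifnot(sigma >= 0, dx > 0, n_hw >= 0)
  k <- seq(-n_hw, n_hw)
  if (sigma == 0) {
    w <- as.numeric(k == 0)
  } else {
    w <- exp(-(k * dx)^2 / (2 * sigma^2))
    # mass of the continuous Gaussian beyond the truncated support
    tail <- 2 * stats::pnorm((n_hw + 0.5) * dx, sd = sigma, lower.tail = FALSE)
    if (tail > 1e-3)
      warning(sprintf(paste0("Gaussian kernel truncates %.2g of its mass at ",
                             "n_hw = %d (sigma/dx = %.3g); increase n_hw or ",
                             "the grid resolution"), tail, n_hw, sigma / dx),
              call. = FALSE)
  }
  new_kernel(w, sigma, dx, "gaussian")
}

#' @rdname diffusion_kernels
#' @export
bessel_kernel <- function(sigma, dx, n_hw = default_n_hw(sigma, dx)) {
  stopifnot(sigma >= 0, dx > 0, n_hw >= 0)
  t <- (sigma / dx)^2
  ord <- seq(-n_hw, n_hw)
  # exp(-t) I_n(t), computed with the exponentially scaled Bessel function
  w <- besselI(t, abs(ord), expon.scaled = TRUE)
  deficiency <- 1 - sum(w)
  if (deficiency > 1e-3)
    warning(sprintf(paste0("Bessel kernel truncates %.2g of its mass at ",
                           "n_hw = %d (t = %.3g); increase n_hw or the grid ",
                           "resolution"), deficiency, n_hw, t), call. = FALSE)
  new_kernel(w, sigma, dx, "bessel")
}

#' Effective kernel length
#'
#' Number of kernel weights above `frac` of the peak weight; a value of 3 or
#' fewer indicates a near-delta kernel that produces essentially no
#' diffusion effect.
#'
#' @param kernel a `diffusion_kernel`.
#' @param frac threshold as a fraction of the maximum weight.
#' @return Integer count.
#' @export
kernel_effective_length <- function(kernel, frac = 1e-2) {
  sum(kernel$weights > frac * max(kernel$weights))
}

#' @export
print.diffusion_kernel <- function(x, ...) {
  cat(sprintf("diffusion_kernel (%s): %d elements, sigma/dx = %.3g, %d effective\n",
              x$kind, length(x$weights), x$sigma / x$dx,
              kernel_effective_length(x)))
  invisible(x)
}

#' Magnetization grid for deterministic diffusion
#'
#' @param spec a gridded 2D [voxel_spec()].
#' @param mxy complex transverse magnetization per element (default 0).
#' @param mz longitudinal magnetization per element (default 1, equilibrium).
#' @return A `magnetization_grid`.
#' @export
magnetization_grid <- function(spec, mxy = NULL, mz = NULL) {
  stopifnot(spec$representation == "gridded", spec$ndim == 2L)
  shape <- c(spec$N, spec$N)
  if (is.null(mxy)) mxy <- matrix(complex(real = 0), shape[1], shape[2])
  if (is.null(mz)) mz <- matrix(1, shape[1], shape[2])
  stopifnot(identical(dim(mxy), as.integer(shape)),
            identical(dim(mz), as.integer(shape)))
  structure(list(mxy = mxy, mz = mz, spec = spec),
            class = "magnetization_grid")
}

#' One deterministic diffusion step
#'
#' Convolves the transverse and longitudinal magnetization grids with the
#' separable diffusion kernel under periodic boundary conditions (the voxel
#' is padded with itself, matching the periodic wrap of the Monte Carlo
#' walker). With `impermeable = TRUE` the kernel weight that would carry
#' magnetization across the tissue boundary between the perturber union (IV)
#' and the rest of the voxel (EV) is retained at its source element, so the
#' total magnetization of each tissue class is conserved exactly:
#' `M'(p) = conv(M * mask_c)(p) + M(p) * conv(mask_notc)(p)` for `p` in
#' class `c`.
#'
#' @param M a [magnetization_grid()].
#' @param kernel a `diffusion_kernel`.
#' @param gv the [gridded_voxel()] supplying compartment labels.
#' @param impermeable logical; the deterministic backend supports only fully
#'   permeable or fully impermeable walls, so requesting it while some
#'   perturber has `0 < perm < 1` is an error.
#' @return The diffused `magnetization_grid`.
#' @export
dd_step <- function(M, kernel, gv = NULL, impermeable = FALSE) {
  w <- kernel$weights
  # a spatially constant mz is a fixed point of the unit-sum convolution
  # (also of the impermeable correction), so skip the work
  mz_const <- diff(range(M$mz)) == 0
  if (!impermeable) {
    M$mxy <- conv_sep_periodic_cx(M$mxy, w)
    if (!mz_const) M$mz <- conv_sep_periodic_re(M$mz, w)
    return(M)
  }
  if (is.null(gv)) stop("impermeable correction requires the gridded voxel")
  if (length(gv$perm) && any(gv$perm > 0 & gv$perm < 1))
    stop("deterministic diffusion supports only perm = 0 or 1; intermediate permeability is not implemented")
  iv <- gv$label > 0L
  masks <- dd_masks(gv, w)
  # weight that would leave an element's own class, retained at the source:
  # for p in EV that is conv(mask_IV)(p), and vice versa (symmetric kernel)
  stay_ev <- masks$conv_iv
  stay_iv <- masks$conv_ev
  conv_ev <- conv_sep_periodic_cx(M$mxy * !iv, w)
  conv_iv <- conv_sep_periodic_cx(M$mxy * iv, w)
  out <- M$mxy * 0
  out[!iv] <- conv_ev[!iv] + M$mxy[!iv] * stay_ev[!iv]
  out[iv] <- conv_iv[iv] + M$mxy[iv] * stay_iv[iv]
  M$mxy <- out
  if (!mz_const) {
    cz_ev <- conv_sep_periodic_re(M$mz * !iv, w)
    cz_iv <- conv_sep_periodic_re(M$mz * iv, w)
    outz <- M$mz * 0
    outz[!iv] <- cz_ev[!iv] + M$mz[!iv] * stay_ev[!iv]
    outz[iv] <- cz_iv[iv] + M$mz[iv] * stay_iv[iv]
    M$mz <- outz
  }
  M
}

# cached convolutions of the class masks (geometry- and kernel-dependent)
dd_masks <- function(gv, w) {
  key <- attr(gv, "dd_mask_cache")
  if (!is.null(key) && identical(key$w, w)) return(key)
  iv <- gv$label > 0L
  res <- list(conv_ev = conv_sep_periodic_re((!iv) * 1, w),
              conv_iv = conv_sep_periodic_re(iv * 1, w),
              w = w)
  res
}
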