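#' Proton gyromagnetic ratio
#'
#' Default gyromagnetic ratio used throughout the simulator, in rad/s/T.
#' All lengths in the package are in mm, times in s and fields in tesla.
#'
#' @return The proton gyromagnetic ratio, 2.6752218744e8 rad/s/T.
#' @export
default_gamma <- function() 2.6752218744e8

#' Convert a ppm (cgs) susceptibility to a dimensionless SI susceptibility
#'
#' Literature values for blood and myelin susceptibility differences are
#' usually quoted in ppm on the cgs scale; the dipole field expressions used
#' here take the dimensionless SI susceptibility, chi_SI = 4 * pi * chi_cgs.
#'
#' @param ppm susceptibility in ppm, cgs convention (e.g. 0.3 for
#'   deoxygenated blood, -0.15 for myelin).
#' @return Dimensionless SI susceptibility difference.
#' @examples
#' ppm_cgs_to_si(0.3) # ~3.77e-6
#' @export
ppm_cgs_to_si <- function(ppm) 4 * pi * ppm * 1e-6

# deterministic child-seed derivation so that each random component of a run
# consumes an independent stream derived from the one user-facing seed
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}
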