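#' Parse and validate a simulation method name
#'
#' Methods are named by hyphenated tokens, one per pipeline component:
#' dimensionality (`2D`/`3D`), space (`CTN` continuous / `GRD` gridded),
#' perturber class (`CYL` cylinders / `SPH` spheres / `VAN` custom mask),
#' field calculation (`ANA` analytic / `FFT` Fourier convolution) and
#' diffusion backend (`MC` Monte Carlo / `DD` deterministic), e.g.
#' `"3D-CTN-CYL-ANA-MC"`. Not all combinations are compatible:
#'
#' * `FFT` requires a gridded voxel (`GRD`) and is only available in 3D
#'   (the dipole convolution kernel is 3D);
#' * custom masks (`VAN`) require the `FFT` field method and 3D;
#' * deterministic diffusion (`DD`) requires a 2D gridded voxel;
#' * spheres (`SPH`) are only available in 3D.
#'
#' @param s method name string.
#' @return A `method_selector` list with fields `ndim`, `space`, `perturber`,
#'   `field`, `diffusion`, `name`; invalid names fail with a message naming
#'   the violated rule.
#' @examples
#' parse_method_name("3D-CTN-CYL-ANA-MC")
#' parse_method_name("2D-GRD-CYL-ANA-DD")
#' @export
parse_method_name <- function(s) {
  tok <- strsplit(toupper(trimws(s)), "-", fixed = TRUE)[[1]]
  if (length(tok) != 5L)
    stop("method name must have 5 hyphen-separated tokens, got: ", s)
  expect <- list(c("2D", "3D"), c("CTN", "GRD"), c("CYL", "SPH", "VAN"),
                 c("ANA", "FFT"), c("MC", "DD"))
  slots <- c("dimensionality", "space", "perturber", "field", "diffusion")
  for (i in seq_len(5)) {
    if (!(tok[i] %in% expect[[i]]))
      stop(sprintf("unknown %s token '%s' (expected one of: %s)",
                   slots[i], tok[i], paste(expect[[i]], collapse = ", ")))
  }
  ndim <- if (tok[1] == "2D") 2L else 3L
  if (tok[4] == "FFT" && tok[2] != "GRD")
    stop("invalid method '", s, "': FFT field calculation requires a gridded (GRD) voxel")
  if (tok[4] == "FFT" && ndim != 3L)
    stop("invalid method '", s, "': FFT field calculation is only available in 3D (the dipole kernel is 3D)")
  if (tok[3] == "VAN" && tok[4] != "FFT")
    stop("invalid method '", s, "': custom masks (VAN) require the FFT field method")
  if (tok[3] == "VAN" && (tok[2] != "GRD" || ndim != 3L))
    stop("invalid method '", s, "': custom masks (VAN) require a 3D gridded voxel")
  if (tok[5] == "DD" && (ndim != 2L || tok[2] != "GRD"))
    stop("invalid method '", s, "': deterministic diffusion (DD) requires a 2D gridded voxel")
  if (tok[3] == "SPH" && ndim != 3L)
    stop("invalid method '", s, "': spheres (SPH) are only available in 3D")
  structure(list(ndim = ndim, space = tok[2], perturber = tok[3],
                 field = tok[4], diffusion = tok[5],
                 name = paste(tok, collapse = "-")),
            class = "method_selector")
}

#' @export
print.method_selector <- function(x, ...) {
  cat("method_selector:", x$name, "\n")
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' The file holds the scalar arguments of [sim_config()] plus nested
#' `voxel:` (ndim, W, representation, N, B0, B0_dir) and `sequence:` (kind,
#' te, dt, tau_shift) blocks and an optional `perturbers:` path to a CSV
#' written by [write_perturbers()]. Arguments in `overrides` take precedence
#' over file values.
#'
#' @param path YAML file.
#' @param overrides named list of config keys overriding the file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(cfg, overrides)
  vs <- do.call(voxel_spec, cfg$voxel)
  sq <- do.call(build_sequence, cfg$sequence)
  pert <- if (!is.null(cfg$perturbers)) {
    if (is.character(cfg$perturbers)) read_perturbers(cfg$perturbers) else cfg$perturbers
  }
  keep <- intersect(names(cfg), c("method", "D", "nspins", "placement",
                                  "tissue", "gamma", "pad", "kernel", "n_hw",
                                  "seed"))
  do.call(sim_config, c(list(spec = vs, sequence = sq, perturbers = pert),
                        cfg[keep]))
}

#' Write a simulation configuration to YAML
#'
#' @param config a `sim_config`.
#' @param path output YAML file.
#' @param perturbers_path optional CSV path; if given, the config's perturber
#'   set is written there and referenced from the YAML.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path, perturbers_path = NULL) {
  spec <- config$spec
  out <- list(
    method = config$method,
    voxel = list(ndim = spec$ndim, W = spec$W,
                 representation = spec$representation,
                 N = spec$N, B0 = spec$B0, B0_dir = as.numeric(spec$B0_dir)),
    sequence = list(kind = config$sequence$kind, te = config$sequence$te,
                    dt = config$sequence$dt),
    D = config$D, nspins = config$nspins, placement = config$placement,
    gamma = config$gamma, kernel = config$kernel, seed = config$seed)
  if (!is.null(config$tissue)) out$tissue <- config$tissue
  if (!is.null(config$n_hw)) out$n_hw <- config$n_hw
  if (!identical(config$pad, "full")) out$pad <- config$pad
  if (!is.null(perturbers_path) && !is.null(config$perturbers)) {
    write_perturbers(config$perturbers, perturbers_path)
    out$perturbers <- perturbers_path
  }
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}
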