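#' Assemble a simulation configuration
#'
#' Collects every ingredient of a forward simulation: the method name (see
#' [parse_method_name()]), the voxel, the perturbers (or a pre-discretized
#' [gridded_voxel()] for custom masks and voxel reuse), the pulse sequence,
#' the diffusion coefficient and, for Monte Carlo, the ensemble size.
#' Consistency between the method name and the supplied pieces is validated
#' by [run_simulation()].
#'
#' @param method method name string, e.g. `"2D-CTN-CYL-ANA-MC"`.
#' @param spec a [voxel_spec()].
#' @param sequence a [build_sequence()] / [custom_sequence()] timing.
#' @param perturbers a `perturber_set` (CYL/SPH methods).
#' @param voxel optional [gridded_voxel()]; required for VAN, otherwise an
#'   alternative to discretizing `perturbers` on the fly.
#' @param D diffusion coefficient (mm^2/s).
#' @param nspins Monte Carlo ensemble size (MC methods).
#' @param placement spin placement, see [init_spins()].
#' @param tissue optional list with `t2` and/or `t1`: numeric vectors of
#'   per-compartment relaxation times (s), indexed `label + 1` (first entry
#'   is the extravascular space, following entries the perturber
#'   compartments, recycled). Absent times mean no decay.
#' @param gamma gyromagnetic ratio (rad/s/T).
#' @param pad FFT zero padding, see [fft_field()].
#' @param kernel deterministic diffusion kernel kind, `"gaussian"` or
#'   `"bessel"`.
#' @param n_hw optional kernel half-width override.
#' @param seed integer seed controlling every random component of the run.
#' @return A `sim_config`.
#' @export
sim_config <- function(method, spec, sequence, perturbers = NULL,
                       voxel = NULL, D = 0, nspins = NULL,
                       placement = "uniform", tissue = NULL,
                       gamma = default_gamma(), pad = "full",
                       kernel = c("gaussian", "bessel"), n_hw = NULL,
                       seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(spec, "voxel_spec"), inherits(sequence, "sequence_timing"))
  structure(list(method = method, spec = spec, sequence = sequence,
                 perturbers = perturbers, voxel = voxel, D = D,
                 nspins = nspins, placement = placement, tissue = tissue,
                 gamma = gamma, pad = pad, kernel = kernel, n_hw = n_hw,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# compact deterministic identifier of a configuration
config_hash <- function(config) {
  r <- serialize(config, NULL, version = 2)
  h <- 2166136261
  for (chunk in split(as.integer(r), ceiling(seq_along(r) / 4096))) {
    h <- (h * 16777619 + sum(chunk * seq_along(chunk))) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# per-site relaxation time from compartment label: entry 1 is the EV space,
# following entries the perturber compartments (recycled over labels)
tissue_at <- function(tvec, label) {
  if (is.null(tvec)) return(NULL)
  if (length(tvec) == 1L) return(rep(tvec, length(label)))
  idx <- ifelse(label == 0L, 1L, 2L + (label - 1L) %% (length(tvec) - 1L))
  tvec[idx]
}

#' Run a forward simulation
#'
#' Executes the full time-stepped loop for the configured method: scheduled
#' RF pulses, a diffusion update (Monte Carlo step or deterministic
#' convolution), field sampling, precession/relaxation, and signal
#' recording, at every step. The run is deterministic given `config$seed`.
#'
#' Method compatibility (FFT requires a 3D gridded voxel, custom masks
#' require FFT, DD requires a 2D gridded voxel, spheres require 3D) is
#' enforced; incompatible configurations fail before any computation.
#'
#' @param config a [sim_config()].
#' @return A `bold_signal`: complex total/IV/EV signal at each time step
#'   (step 0 is immediately after excitation, unnormalized so
#'   `|total| = nspins` resp. the grid-element count), with method, seed and
#'   configuration-hash metadata.
#' @export
run_simulation <- function(config) {
  sel <- parse_method_name(config$method)
  spec <- config$spec
  if (sel$ndim != spec$ndim)
    stop(sprintf("method %s is %dD but the voxel spec is %dD",
                 sel$name, sel$ndim, spec$ndim))
  if (sel$space == "GRD" && spec$representation != "gridded")
    stop("method ", sel$name, " needs a gridded voxel spec")
  if (sel$space == "CTN" && spec$representation != "continuous")
    stop("method ", sel$name, " needs a continuous voxel spec")
  if (sel$perturber == "VAN" && is.null(config$voxel))
    stop("custom-mask (VAN) methods need a pre-built gridded voxel")
  if (sel$perturber != "VAN" && is.null(config$perturbers))
    stop("method ", sel$name, " needs a perturber set")
  if (!is.null(config$perturbers)) {
    want <- c(CYL = if (sel$ndim == 2L) "cylinder2d" else "cylinder3d",
              SPH = "sphere3d", VAN = NA)[[sel$perturber]]
    if (!is.na(want) && pert_kind(config$perturbers) != want)
      stop(sprintf("method %s expects %s perturbers, got %s",
                   sel$name, want, pert_kind(config$perturbers)))
  }

  gv <- NULL
  if (sel$space == "GRD") {
    gv <- config$voxel
    if (is.null(gv)) gv <- discretize_voxel(config$perturbers, spec)
  }
  field_grid <- NULL
  if (sel$field == "FFT") {
    field_grid <- fft_field(gv, pad = config$pad)
  } else if (sel$space == "GRD") {
    field_grid <- analytic_field_grid(config$perturbers, spec)
  }

  if (sel$diffusion == "MC") {
    run_mc(config, sel, gv, field_grid)
  } else {
    run_dd(config, sel, gv, field_grid)
  }
}

run_mc <- function(config, sel, gv, field_grid) {
  spec <- config$spec
  seq_ <- config$sequence
  if (is.null(config$nspins)) stop("Monte Carlo methods need nspins")
  geom <- if (!is.null(gv)) gv else config$perturbers
  ens <- init_spins(config$nspins, spec, geom,
                    seed = derive_seed(config$seed, "init"),
                    placement = config$placement)
  dcfg <- diffusion_config(config$D, seq_$dt)
  analytic_src <- sel$field == "ANA" && sel$space == "CTN"
  field_is_zero <- if (analytic_src) {
    nrow(config$perturbers) == 0L || all(config$perturbers$dchi == 0)
  } else {
    all(field_grid$values == 0)
  }
  static <- dcfg$sigma == 0
  static_dbz <- NULL
  t2v <- config$tissue$t2
  t1v <- config$tissue$t1

  n_rec <- seq_$n_steps + 1L
  sig <- matrix(complex(real = 0), n_rec, 3)
  pulse_steps <- vapply(seq_$pulses, `[[`, integer(1), "step")

  set.seed(derive_seed(config$seed, "walk"))
  for (j in 0:seq_$n_steps) {
    if (j > 0) {
      ens <- mc_step(ens, dcfg, geom)
      dbz <- if (field_is_zero) {
        0
      } else if (static && !is.null(static_dbz)) {
        static_dbz
      } else if (analytic_src) {
        sample_field(ens, config$perturbers, spec$B0, spec$B0_dir)
      } else {
        sample_field(ens, field_grid)
      }
      if (static && is.null(static_dbz) && !field_is_zero) static_dbz <- dbz
      ev <- evolve_step(ens$mxy, ens$mz, dbz, seq_$dt,
                        tissue_at(t2v, ens$label), tissue_at(t1v, ens$label),
                        config$gamma)
      ens$mxy <- ev$mxy
      ens$mz <- ev$mz
    }
    # a pulse scheduled at step j acts at time j * dt, after that step's
    # evolution and just before the magnetization is read out, so an SE
    # refocusing pulse at step TE/2/dt splits the phase history evenly
    for (p in seq_$pulses[pulse_steps == j]) {
      rot <- apply_rf(ens$mxy, ens$mz, p)
      ens$mxy <- rot$mxy
      ens$mz <- rot$mz
    }
    sig[j + 1L, ] <- sum_signal(ens$mxy, ens$label)
  }
  new_bold_signal(sig, seq_, config, n_sites = config$nspins,
                  extra = list(n_stuck = ens$n_stuck))
}

run_dd <- function(config, sel, gv, field_grid) {
  spec <- config$spec
  seq_ <- config$sequence
  perm <- gv$perm
  if (length(perm) && any(perm > 0 & perm < 1))
    stop("deterministic diffusion supports only perm = 0 or 1")
  if (length(perm) && any(perm == 0) && any(perm == 1))
    stop("deterministic diffusion needs a single wall behaviour: all perturbers perm = 0 or all perm = 1")
  impermeable <- length(perm) > 0 && all(perm == 0) && any(gv$label > 0L)
  dcfg <- diffusion_config(config$D, seq_$dt)
  kern_fn <- if (config$kernel == "bessel") bessel_kernel else gaussian_kernel
  kernel <- if (is.null(config$n_hw)) kern_fn(dcfg$sigma, grid_dx(spec)) else
    kern_fn(dcfg$sigma, grid_dx(spec), config$n_hw)
  attr(gv, "dd_mask_cache") <- dd_masks(gv, kernel$weights)

  M <- magnetization_grid(spec)
  lab <- gv$label
  field_is_zero <- all(field_grid$values == 0)
  ph <- if (field_is_zero) NULL else
    exp(complex(imaginary = config$gamma * seq_$dt) * field_grid$values)
  t2map <- if (!is.null(config$tissue$t2)) {
    array(tissue_at(config$tissue$t2, as.vector(lab)), dim = dim(lab))
  }
  t1map <- if (!is.null(config$tissue$t1)) {
    array(tissue_at(config$tissue$t1, as.vector(lab)), dim = dim(lab))
  }
  decay <- if (!is.null(t2map)) exp(-seq_$dt / t2map)
  diffusing <- dcfg$sigma > 0

  n_rec <- seq_$n_steps + 1L
  sig <- matrix(complex(real = 0), n_rec, 3)
  pulse_steps <- vapply(seq_$pulses, `[[`, integer(1), "step")

  for (j in 0:seq_$n_steps) {
    if (j > 0) {
      if (diffusing) M <- dd_step(M, kernel, gv, impermeable)
      if (!is.null(ph)) M$mxy <- M$mxy * ph
      if (!is.null(decay)) M$mxy <- M$mxy * decay
      if (!is.null(t1map)) M$mz <- 1 + (M$mz - 1) * exp(-seq_$dt / t1map)
    }
    for (p in seq_$pulses[pulse_steps == j]) {
      rot <- apply_rf(M$mxy, M$mz, p)
      M$mxy <- rot$mxy
      M$mz <- rot$mz
    }
    sig[j + 1L, ] <- sum_signal(M$mxy, lab)
  }
  new_bold_signal(sig, seq_, config, n_sites = length(lab),
                  extra = list(kernel = kernel$kind,
                               kernel_elements = length(kernel$weights),
                               impermeable = impermeable))
}

new_bold_signal <- function(sig, seq_, config, n_sites, extra = list()) {
  structure(list(time = (0:seq_$n_steps) * seq_$dt,
                 total = sig[, 1], iv = sig[, 2], ev = sig[, 3],
                 n_sites = n_sites,
                 method = config$method,
                 seed = config$seed,
                 te = seq_$te,
                 sequence_kind = seq_$kind,
                 config_hash = config_hash(config),
                 extra = extra),
            class = "bold_signal")
}

#' @export
print.bold_signal <- function(x, ...) {
  cat(sprintf("bold_signal: %s (%s), %d steps of %g ms, %d sites [seed %d, config %s]\n",
              x$method, x$sequence_kind, length(x$time) - 1L,
              diff(x$time[1:2]) * 1e3, x$n_sites, x$seed, x$config_hash))
  cat(sprintf("  |S| at t=0: %.6g; at TE=%g ms: %.6g (%.4f of initial)\n",
              Mod(x$total[1]), x$te * 1e3, Mod(x$total[length(x$total)]),
              Mod(x$total[length(x$total)]) / Mod(x$total[1])))
  invisible(x)
}

#' @export
as.data.frame.bold_signal <- function(x, ...) {
  data.frame(time = x$time,
             re_total = Re(x$total), im_total = Im(x$total),
             re_iv = Re(x$iv), im_iv = Im(x$iv),
             re_ev = Re(x$ev), im_ev = Im(x$ev))
}

#' @export
plot.bold_signal <- function(x, normalize = TRUE, ...) {
  s0 <- if (normalize) Mod(x$total[1]) else 1
  plot(x$time * 1e3, Mod(x$total) / s0, type = "l", lwd = 2,
       xlab = "time (ms)", ylab = if (normalize) "|S| / |S(0)|" else "|S|",
       main = x$method, ...)
  lines(x$time * 1e3, Mod(x$iv) / s0, lty = 2)
  lines(x$time * 1e3, Mod(x$ev) / s0, lty = 3)
  legend("bottomleft", c("total", "IV", "EV"), lty = 1:3, bty = "n")
  invisible(x)
}

#' Write / read a signal time course as columnar text
#'
#' Columns `time, re_total, im_total, re_iv, im_iv, re_ev, im_ev`, preceded
#' by `#` metadata lines (method, seed, config hash, site count) sufficient
#' to reproduce the run.
#'
#' @param sig a `bold_signal`.
#' @param path output file.
#' @return `write_signal` returns `path` invisibly; `read_signal` returns a
#'   `bold_signal`.
#' @export
write_signal <- function(sig, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# boldsim_signal v1",
               sprintf("# method: %s", sig$method),
               sprintf("# sequence: %s", sig$sequence_kind),
               sprintf("# seed: %d", sig$seed),
               sprintf("# config_hash: %s", sig$config_hash),
               sprintf("# n_sites: %d", sig$n_sites),
               sprintf("# te: %.17g", sig$te)), con)
  utils::write.table(format(as.data.frame(sig), digits = 17), con,
                     row.names = FALSE, quote = FALSE, sep = ",")
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  lines <- readLines(path, n = 16L)
  get <- function(key) {
    l <- grep(sprintf("^# %s: ", key), lines, value = TRUE)[1]
    sub(sprintf("^# %s: ", key), "", l)
  }
  d <- utils::read.csv(path, comment.char = "#")
  structure(list(time = d$time,
                 total = complex(real = d$re_total, imaginary = d$im_total),
                 iv = complex(real = d$re_iv, imaginary = d$im_iv),
                 ev = complex(real = d$re_ev, imaginary = d$im_ev),
                 n_sites = as.integer(get("n_sites")),
                 method = get("method"),
                 seed = as.integer(get("seed")),
                 te = as.numeric(get("te")),
                 sequence_kind = get("sequence"),
                 config_hash = get("config_hash"),
                 extra = list()),
            class = "bold_signal")
}
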