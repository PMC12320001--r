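#' RF pulse
#'
#' A hard pulse rotating the magnetization by flip angle `alpha` about an
#' axis given in polar coordinates: `axis_polar` from +z and `axis_azimuth`
#' from +x, so a pulse along x is `(pi/2, 0)` and along y is `(pi/2, pi/2)`.
#' Rotations follow the right-hand rule about the pulse axis. A pulse
#' scheduled at time step `step` acts at time `step * dt`: after that step's
#' diffusion and precession update and just before the magnetization is
#' read out, so a refocusing pulse at step `TE/2/dt` splits the phase
#' history into equal halves.
#'
#' @param alpha flip angle (rad).
#' @param axis_polar polar angle of the rotation axis from +z (rad).
#' @param axis_azimuth azimuth of the rotation axis from +x (rad).
#' @param step time-step index at which the pulse is applied (0 = before the
#'   first evolution step).
#' @return An `rf_pulse`.
#' @export
rf_pulse <- function(alpha, axis_polar = pi / 2, axis_azimuth = 0, step = 0L) {
  stopifnot(step >= 0)
  structure(list(alpha = alpha, axis_polar = axis_polar,
                 axis_azimuth = axis_azimuth, step = as.integer(step)),
            class = "rf_pulse")
}

#' Build a standard pulse sequence
#'
#' `GE` is excitation only (90 degrees about x at step 0); `SE` adds a
#' 180-degree refocusing pulse about y at `TE/2`; `ASE` displaces the
#' refocusing pulse to `TE/2 + tau_shift` while still sampling at `TE`
#' (`tau_shift = 0` reduces to SE). All times must be integer multiples of
#' `dt`.
#'
#' @param kind `"GE"`, `"SE"` or `"ASE"`.
#' @param te echo time (s); the simulation runs for `te / dt` steps.
#' @param dt time step (s).
#' @param tau_shift refocusing-pulse displacement from `TE/2` (s, ASE only).
#' @return A `sequence_timing`: list with `dt`, `n_steps`, `te`, `kind`,
#'   `pulses`.
#' @export
build_sequence <- function(kind = c("GE", "SE", "ASE"), te, dt,
                           tau_shift = 0) {
  kind <- match.arg(kind)
  steps_of <- function(t, what) {
    n <- t / dt
    if (abs(n - round(n)) > 1e-6)
      stop(sprintf("%s = %g s is not a multiple of dt = %g s (remainder %g s)",
                   what, t, dt, t - round(n) * dt))
    as.integer(round(n))
  }
  n_steps <- steps_of(te, "TE")
  pulses <- list(rf_pulse(pi / 2, pi / 2, 0, step = 0L))
  if (kind %in% c("SE", "ASE")) {
    shift <- if (kind == "ASE") tau_shift else 0
    refocus_step <- steps_of(te / 2 + shift, "TE/2 + tau_shift")
    if (refocus_step < 0 || refocus_step > n_steps)
      stop("refocusing pulse falls outside the sequence")
    pulses <- c(pulses, list(rf_pulse(pi, pi / 2, pi / 2, step = refocus_step)))
  }
  structure(list(dt = dt, n_steps = n_steps, te = te, kind = kind,
                 pulses = pulses), class = "sequence_timing")
}

#' Custom pulse list
#'
#' Assemble a sequence from arbitrary [rf_pulse()] objects (e.g. manual
#' refocusing trains).
#'
#' @param dt time step (s).
#' @param n_steps number of evolution steps.
#' @param pulses list of [rf_pulse()].
#' @return A `sequence_timing`.
#' @export
custom_sequence <- function(dt, n_steps, pulses) {
  stopifnot(all(vapply(pulses, inherits, logical(1), "rf_pulse")))
  steps <- vapply(pulses, `[[`, integer(1), "step")
  if (any(steps > n_steps)) stop("pulse step_index exceeds n_steps")
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 te = dt * n_steps, kind = "custom", pulses = pulses),
            class = "sequence_timing")
}

# Rodrigues rotation matrix about a unit axis, right-hand rule
rotation_matrix <- function(axis_polar, axis_azimuth, alpha) {
  u <- c(sin(axis_polar) * cos(axis_azimuth),
         sin(axis_polar) * sin(axis_azimuth),
         cos(axis_polar))
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(alpha) * K + (1 - cos(alpha)) * (K %*% K)
}

#' Apply an RF pulse to magnetization
#'
#' Rotates each magnetization vector `(Mx, My, Mz)` by the pulse flip angle
#' about the pulse axis (right-hand rule).
#'
#' @param mxy complex transverse magnetization (vector, matrix or array).
#' @param mz longitudinal magnetization, same shape.
#' @param pulse an [rf_pulse()].
#' @return List with rotated `mxy` and `mz`.
#' @export
apply_rf <- function(mxy, mz, pulse) {
  R <- rotation_matrix(pulse$axis_polar, pulse$axis_azimuth, pulse$alpha)
  M <- rbind(as.vector(Re(mxy)), as.vector(Im(mxy)), as.vector(mz))
  M2 <- R %*% M
  out_xy <- complex(real = M2[1, ], imaginary = M2[2, ])
  out_z <- M2[3, ]
  if (!is.null(dim(mxy))) {
    dim(out_xy) <- dim(mxy)
    dim(out_z) <- dim(mz)
  }
  list(mxy = out_xy, mz = out_z)
}

#' One precession/relaxation step
#'
#' Applies the phase increment `gamma * dBz * dt` as a complex rotation of
#' the transverse magnetization, transverse decay `exp(-dt / T2)` where a T2
#' is given, and longitudinal recovery toward equilibrium 1 with time
#' constant T1 where given. Absent relaxation times mean no decay.
#'
#' @param mxy,mz magnetization (any shape).
#' @param dbz per-site field offset (T), same shape as `mxy`.
#' @param dt time step (s).
#' @param t2,t1 per-site relaxation times (s) or `NULL`.
#' @param gamma gyromagnetic ratio (rad/s/T).
#' @return List with updated `mxy` and `mz`.
#' @export
evolve_step <- function(mxy, mz, dbz, dt, t2 = NULL, t1 = NULL,
                        gamma = default_gamma()) {
  rot <- exp(complex(imaginary = gamma * dt) * dbz)
  if (!is.null(t2)) rot <- rot * exp(-dt / t2)
  mxy <- mxy * rot
  if (!is.null(t1)) mz <- 1 + (mz - 1) * exp(-dt / t1)
  list(mxy = mxy, mz = mz)
}

#' Total, intravascular and extravascular complex signal
#'
#' @param mxy complex transverse magnetization per site.
#' @param labels compartment label per site (0 = EV).
#' @return Named complex vector `c(total, iv, ev)`; `total = iv + ev`
#'   exactly.
#' @export
sum_signal <- function(mxy, labels) {
  iv <- sum(mxy[labels > 0L])
  ev <- sum(mxy[labels == 0L])
  c(total = iv + ev, iv = iv, ev = ev)
}
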