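#' External-current forcing protocols
#'
#' A constant protocol applies `I0`; a sinusoidal protocol applies
#' `I_ext(t) = I0 (1 + B sin(omega t + phase0))`, the subthreshold periodic
#' drive studied throughout the package.  With `I0` above the quiescence
#' current `I*` and `B` inside [admissible_amplitude_range()], the forcing
#' stays in the non-spiking region at all times, so any firing it evokes is
#' a genuine resonance effect.
#'
#' @param kind `"constant"` or `"sinusoidal"`.
#' @param I0 base current (uA/cm^2).
#' @param B relative amplitude (dimensionless, >= 0).
#' @param omega angular frequency (rad/ms).
#' @param phase0 initial phase (rad); every run starts at `phase0` at `t = 0`.
#' @return An object of class `hb_protocol`.
#' @export
forcing_protocol <- function(kind = c("constant", "sinusoidal"),
                             I0, B = 0, omega = 0, phase0 = 0) {
  kind <- match.arg(kind)
  if (kind == "sinusoidal") {
    if (B < 0) stop("B must be >= 0")
    if (omega <= 0) stop("omega must be > 0 for a sinusoidal protocol")
  }
  structure(list(kind = kind, I0 = I0, B = B, omega = omega, phase0 = phase0),
            class = "hb_protocol")
}

#' @export
print.hb_protocol <- function(x, ...) {
  if (x$kind == "constant") {
    cat(sprintf("constant forcing: I_ext = %g uA/cm^2\n", x$I0))
  } else {
    cat(sprintf(
      "sinusoidal forcing: I_ext(t) = %g (1 + %g sin(%g t + %g)) uA/cm^2\n",
      x$I0, x$B, x$omega, x$phase0))
  }
  invisible(x)
}

#' Evaluate the external current of a protocol
#'
#' @param t time(s) (ms).
#' @param protocol an [forcing_protocol()] object.
#' @return Current(s) in uA/cm^2.
#' @export
external_current <- function(t, protocol) {
  if (protocol$kind == "constant") return(rep_len(protocol$I0, length(t)))
  protocol$I0 * (1 + protocol$B * sin(protocol$omega * t + protocol$phase0))
}

#' Admissible forcing amplitudes
#'
#' For base current `I0` above the quiescence current `I_star`, the forcing
#' stays in the non-spiking region for all `t` when `0 < B < 1 - I_star/I0`
#' (the sine minimum `I0 (1 - B)` then stays above `I_star`).
#'
#' @param I0 base current (uA/cm^2).
#' @param I_star quiescence (critical) current (uA/cm^2), default 1.42.
#' @return `c(0, B_max)`.
#' @export
admissible_amplitude_range <- function(I0, I_star = 1.42) {
  if (!(I0 > I_star && I_star > 0))
    stop("empty range: need I0 > I_star > 0")
  c(0, 1 - I_star / I0)
}

#' Integration settings
#'
#' Fixed-step RK4 settings.  `t_transient` is integrated and discarded;
#' `t_measure` is integrated with every `record_stride`-th step recorded
#' (including the transient-end sample).  Spans are rounded to whole steps.
#'
#' @param dt time step (ms), default 0.01.
#' @param t_transient discarded initial span (ms).
#' @param t_measure recorded span (ms).
#' @param record_stride keep one sample every this many steps (default 10,
#'   i.e. 0.1 ms sampling at the default step).
#' @return An object of class `hb_config`.
#' @export
integration_config <- function(dt = 0.01, t_transient = 1e5, t_measure = 5e5,
                               record_stride = 10) {
  if (dt <= 0) stop("dt must be > 0")
  if (t_transient < 0 || t_measure <= 0)
    stop("spans must be positive (t_transient may be 0)")
  if (record_stride < 1) stop("record_stride must be >= 1")
  structure(list(dt = dt,
                 t_transient = round(t_transient / dt) * dt,
                 t_measure = round(t_measure / dt) * dt,
                 record_stride = as.integer(record_stride)),
            class = "hb_config")
}

#' One classical RK4 step
#'
#' Reference R implementation of the integrator step (the production loop
#' runs in compiled code; [hb_integrate()] and this function agree to
#' machine precision).  The time-dependent forcing is evaluated at `t`,
#' `t + dt/2` and `t + dt`.
#'
#' @param t current time (ms).
#' @param state an [hb_state()].
#' @param dt step (ms).
#' @param protocol an [forcing_protocol()].
#' @param params an [hb_params()].
#' @return The state after one step.
#' @export
rk4_step <- function(t, state, dt, protocol, params = hb_params()) {
  if (dt <= 0) stop("dt must be > 0")
  s <- as.numeric(as_hb_state(state))
  f <- function(tt, ss) {
    unname(hb_vector_field(tt, ss, external_current(tt, protocol), params))
  }
  k1 <- f(t, s)
  k2 <- f(t + dt / 2, s + dt / 2 * k1)
  k3 <- f(t + dt / 2, s + dt / 2 * k2)
  k4 <- f(t + dt, s + dt * k3)
  out <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (!all(is.finite(out))) stop("integration blow-up at t = ", t + dt, " ms")
  hb_state(out[1], out[2], out[3], out[4])
}

#' Integrate the model
#'
#' Advances the state through `t_transient + t_measure` with fixed-step RK4
#' in compiled code and returns the recorded trajectory.  Spike times can be
#' detected online (upward threshold crossings, linearly interpolated, with a
#' refractory guard) so that sweeps can run without recording samples.
#' The integration is fully deterministic: identical inputs give
#' bit-identical trajectories.
#'
#' @param state0 initial [hb_state()].
#' @param protocol an [forcing_protocol()].
#' @param config an [integration_config()]; set `record_stride` large (or
#'   `record = FALSE`) when only spikes or the end state are needed.
#' @param params an [hb_params()].
#' @param record if `FALSE`, no samples are stored (end state and spikes
#'   only).
#' @param detect_spikes detect spikes online during the measured span.
#' @param threshold,refractory spike criterion (mV, ms); see
#'   [detect_spikes()].
#' @return An object of class `hb_trajectory`: list with vectors `t`, `V`,
#'   `a_r`, `a_sd`, `a_sr`, `i_ext`, the final `end_state`, optional
#'   `spike_times`, and the provenance (`protocol`, `config`, `params`).
#' @examples
#' \donttest{
#' p <- hb_params()
#' pr <- forcing_protocol("constant", I0 = 1.5)
#' cfg <- integration_config(t_transient = 1e3, t_measure = 1e3)
#' tr <- hb_integrate(hb_state(-60, 0, 0, 0.2), pr, cfg, p)
#' range(tr$V)
#' }
#' @export
hb_integrate <- function(state0, protocol, config, params = hb_params(),
                         record = TRUE, detect_spikes = FALSE,
                         threshold = -20, refractory = 20) {
  s0 <- as.numeric(as_hb_state(state0))
  stopifnot(inherits(protocol, "hb_protocol"), inherits(config, "hb_config"))
  B <- if (protocol$kind == "constant") 0 else protocol$B
  omega <- if (protocol$kind == "constant") 0 else protocol$omega
  res <- hb_run_cpp(s0, params_vector(params),
                    protocol$I0, B, omega, protocol$phase0,
                    config$dt,
                    round(config$t_transient / config$dt),
                    round(config$t_measure / config$dt),
                    if (record) config$record_stride else 0L,
                    detect_spikes, threshold, refractory)
  structure(list(t = res$t, V = res$V, a_r = res$a_r, a_sd = res$a_sd,
                 a_sr = res$a_sr, i_ext = res$i_ext,
                 end_state = hb_state(res$end_state[1], res$end_state[2],
                                      res$end_state[3], res$end_state[4]),
                 spike_times = if (detect_spikes) res$spike_times else NULL,
                 threshold = if (detect_spikes) threshold else NULL,
                 refractory = if (detect_spikes) refractory else NULL,
                 protocol = protocol, config = config, params = params),
            class = "hb_trajectory")
}

#' @export
print.hb_trajectory <- function(x, ...) {
  cat(sprintf("hb_trajectory: %d samples over [%g, %g] ms (dt = %g, stride %d)\n",
              length(x$t),
              if (length(x$t)) x$t[1] else NA, if (length(x$t)) x$t[length(x$t)] else NA,
              x$config$dt, x$config$record_stride))
  print(x$protocol)
  if (!is.null(x$spike_times))
    cat(sprintf("  %d spikes detected (threshold %g mV)\n",
                length(x$spike_times), x$threshold))
  invisible(x)
}

# Pure-R integrator over n steps; slow, used only for cross-validation of
# the compiled kernel.
hb_integrate_r <- function(state0, protocol, dt, n_steps,
                           params = hb_params(), t0 = 0) {
  s <- as_hb_state(state0)
  out <- matrix(NA_real_, n_steps + 1, 4)
  out[1, ] <- as.numeric(s)
  for (i in seq_len(n_steps)) {
    s <- rk4_step(t0 + (i - 1) * dt, s, dt, protocol, params)
    out[i + 1, ] <- as.numeric(s)
  }
  colnames(out) <- c("V", "a_r", "a_sd", "a_sr")
  out
}
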