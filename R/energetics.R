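#' Instantaneous energy rates of the equivalent circuit
#'
#' The total power of the equivalent electrical circuit is
#' `H_dot = C_m V dV/dt + I_l V_l + I_d V_d + I_r V_r + I_sd V_sd + I_sr V_sr`.
#' Substituting the membrane equation splits it as
#' `H_dot = supplied + E_c`, where `supplied = -V I_ext` is the power
#' delivered by the external current and
#' `E_c = -[g_l (V - V_l)^2 + sum_x rho g_x a_x (V - V_x)^2]`
#' is the metabolic consumption rate of the ion channels: a negated sum of
#' dissipation terms, hence `E_c <= 0` whenever all activations are
#' nonnegative.  Units: uA/cm^2 x mV = nW/cm^2, i.e. nJ/s per cm^2 of
#' membrane.
#'
#' `H_dot` is computed independently from its defining sum (with `dV/dt`
#' from [hb_vector_field()]), so the identity `H_dot = supplied + E_c`
#' is an algebraic cross-check, not a construction.
#'
#' @param state an [hb_state()] (vectorized input: see
#'   [energy_trace()]).
#' @param i_ext external current (uA/cm^2).
#' @param params an [hb_params()].
#' @return List with `H_dot`, `E_c`, `supplied` (nJ/s per cm^2).
#' @export
energy_rate <- function(state, i_ext, params = hb_params()) {
  s <- as_hb_state(state)
  e <- energy_components(s[[1]], s[[2]], s[[3]], s[[4]], i_ext, params)
  dV <- hb_vector_field(0, s, i_ext, params)[[1]]
  H_dot <- params$C_m * s[[1]] * dV +
    e$I_l * params$V_l + e$I_d * params$V_d + e$I_r * params$V_r +
    e$I_sd * params$V_sd + e$I_sr * params$V_sr
  list(H_dot = H_dot, E_c = e$E_c, supplied = e$supplied)
}

# vectorized core shared by energy_rate and energy_trace
energy_components <- function(V, a_r, a_sd, a_sr, i_ext, params) {
  p <- params
  a_d <- steady_state_activation(V, "d", p)
  I_l <- p$g_l * (V - p$V_l)
  I_d <- p$rho * p$g_d * a_d * (V - p$V_d)
  I_r <- p$rho * p$g_r * a_r * (V - p$V_r)
  I_sd <- p$rho * p$g_sd * a_sd * (V - p$V_sd)
  I_sr <- p$rho * p$g_sr * a_sr * (V - p$V_sr)
  E_c <- -(I_l * (V - p$V_l) + I_d * (V - p$V_d) + I_r * (V - p$V_r) +
             I_sd * (V - p$V_sd) + I_sr * (V - p$V_sr))
  list(I_l = I_l, I_d = I_d, I_r = I_r, I_sd = I_sd, I_sr = I_sr,
       E_c = E_c, supplied = -V * i_ext)
}

#' Energy time series along a trajectory
#'
#' @param traj an [hb_integrate()] trajectory (recorded samples).
#' @param params an [hb_params()]; defaults to the trajectory's own.
#' @return data.frame with `t`, `E_c`, `supplied`, `H_dot` (nJ/s per cm^2).
#' @export
energy_trace <- function(traj, params = NULL) {
  if (is.null(params)) params <- traj$params
  e <- energy_components(traj$V, traj$a_r, traj$a_sd, traj$a_sr,
                         traj$i_ext, params)
  data.frame(t = traj$t, E_c = e$E_c, supplied = e$supplied,
             H_dot = e$supplied + e$E_c)
}

#' Average energy consumption over a window
#'
#' The absolute time average `|1/T int E_c dt|` computed by the trapezoid
#' rule on the recorded samples.  By default the whole recorded span is
#' used; `t_i` and `T_window` select a sub-window, which must lie inside
#' the trajectory.
#'
#' @param traj an [hb_integrate()] trajectory.
#' @param params an [hb_params()]; defaults to the trajectory's own.
#' @param t_i window start (ms, on the trajectory's clock).
#' @param T_window window length (ms).
#' @return An object of class `energy_summary` with `mean_abs` (nJ/s per
#'   cm^2) and the window actually used.
#' @export
average_energy <- function(traj, params = NULL, t_i = NULL, T_window = NULL) {
  if (is.null(params)) params <- traj$params
  tt <- traj$t
  if (is.null(t_i)) t_i <- tt[1]
  if (is.null(T_window)) T_window <- tt[length(tt)] - t_i
  if (t_i < tt[1] - 1e-9 || t_i + T_window > tt[length(tt)] + 1e-9)
    stop("averaging window [", t_i, ", ", t_i + T_window,
         "] lies outside the recorded span")
  sel <- tt >= t_i - 1e-9 & tt <= t_i + T_window + 1e-9
  e <- energy_components(traj$V[sel], traj$a_r[sel], traj$a_sd[sel],
                         traj$a_sr[sel], traj$i_ext[sel], params)$E_c
  ts <- tt[sel]
  m <- sum(diff(ts) * (head(e, -1) + tail(e, -1)) / 2) / (ts[length(ts)] - ts[1])
  structure(list(mean_abs = abs(m), t_i = ts[1],
                 T_window = ts[length(ts)] - ts[1]),
            class = "energy_summary")
}

#' @export
print.energy_summary <- function(x, ...) {
  cat(sprintf("<E_c> = %.4f nJ/s over [%g, %g] ms\n",
              x$mean_abs, x$t_i, x$t_i + x$T_window))
  invisible(x)
}

#' Closed-form energy consumption at a fixed point
#'
#' At an equilibrium the consumption rate is constant, so the long-run
#' average equals `|E_c|` evaluated at the fixed point.
#'
#' @inheritParams find_fixed_point
#' @return `|E_c|` in nJ/s per cm^2.
#' @export
fixed_point_energy <- function(i_ext, params = hb_params()) {
  fp <- find_fixed_point(i_ext, params)
  abs(energy_rate(fp, i_ext, params)$E_c)
}

#' Energy consumption across the resonance region
#'
#' For each forcing frequency, integrates from the stated initial
#' condition, then reports the average energy consumption together with
#' the frequency-locking ratio of the same run.  The averaging window is
#' rounded down to a whole number of forcing periods to suppress
#' windowing bias.
#'
#' @param omega_grid forcing frequencies (rad/ms).
#' @param B forcing amplitude.
#' @param ic initial state.
#' @param I0 base current.
#' @param params an [hb_params()].
#' @param config an [integration_config()]; `record_stride` governs the
#'   trapezoid resolution (default 0.1 ms).
#' @return data.frame with `omega`, `ratio`, `energy` (nJ/s per cm^2).
#' @export
energy_resonance_profile <- function(omega_grid, B, ic, I0 = 1.5,
                                     params = hb_params(),
                                     config = integration_config(
                                       t_transient = 1e5, t_measure = 2e5)) {
  out <- data.frame(omega = omega_grid, ratio = NA_real_, energy = NA_real_)
  for (i in seq_along(omega_grid)) {
    om <- omega_grid[i]
    pr <- forcing_protocol("sinusoidal", I0 = I0, B = B, omega = om)
    tr <- hb_integrate(as_hb_state(ic), pr, config, params,
                       record = TRUE, detect_spikes = TRUE)
    out$ratio[i] <- frequency_ratio(spike_train(tr$spike_times), om)
    period <- 2 * pi / om
    span <- tr$t[length(tr$t)] - tr$t[1]
    T_win <- floor(span / period) * period
    out$energy[i] <- average_energy(tr, params, t_i = tr$t[1],
                                    T_window = T_win)$mean_abs
  }
  out
}

#' Energy comparison of coexisting attractors
#'
#' Runs one simulation per initial condition under identical forcing and
#' tabulates the attractor label next to its average energy consumption;
#' the instrument behind statements like "subthreshold oscillations consume
#' the least energy" among coexisting attractors.
#'
#' @param ics list of initial states.
#' @param omega forcing frequency (rad/ms).
#' @param B forcing amplitude.
#' @param I0 base current.
#' @param params an [hb_params()].
#' @param config an [integration_config()].
#' @param tol,k_max classifier settings, see [classify_attractor()].
#' @return data.frame with one row per IC: `ic` (deparsed), `category`,
#'   `period_k`, `energy`.
#' @export
attractor_energy_comparison <- function(ics, omega, B, I0 = 1.5,
                                        params = hb_params(),
                                        config = integration_config(
                                          t_transient = 1e5, t_measure = 2e5),
                                        tol = 0.01, k_max = 8) {
  rows <- lapply(ics, function(ic) {
    pr <- forcing_protocol("sinusoidal", I0 = I0, B = B, omega = omega)
    tr <- hb_integrate(as_hb_state(ic), pr, config, params,
                       record = TRUE, detect_spikes = TRUE)
    lab <- classify_attractor(isi_sequence(spike_train(tr$spike_times)),
                              tol = tol, k_max = k_max)
    period <- 2 * pi / omega
    span <- tr$t[length(tr$t)] - tr$t[1]
    e <- average_energy(tr, params, t_i = tr$t[1],
                        T_window = floor(span / period) * period)$mean_abs
    data.frame(ic = paste(as.numeric(as_hb_state(ic)), collapse = ","),
               category = lab$category, period_k = lab$period_k,
               energy = e)
  })
  do.call(rbind, rows)
}
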