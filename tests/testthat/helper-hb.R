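# Shared objects for the suite.  The three canonical initial conditions are
# the ones used throughout the multistability analysis.
hb <- hb_params()
IC1 <- hb_state(-60, 0, 0, 0.5)
IC2 <- hb_state(-60, 0, 0, 0.2)
IC3 <- hb_state(-20, 0, 0, 0.2)

# Constant-current quiescent reference point.
I_QUIESCENT <- 1.5

# Short sinusoidal run returning the online-detected spike train.
quick_spikes <- function(ic, omega, B = 0.0475, I0 = 1.5,
                         t_transient = 3e4, t_measure = 6e4, dt = 0.01,
                         params = hb) {
  pr <- forcing_protocol("sinusoidal", I0 = I0, B = B, omega = omega)
  cfg <- integration_config(dt = dt, t_transient = t_transient,
                            t_measure = t_measure)
  tr <- hb_integrate(ic, pr, cfg, params, record = FALSE,
                     detect_spikes = TRUE)
  spike_train(tr$spike_times)
}

# Evenly spaced p:q-locked train: p spikes per q forcing cycles of angular
# frequency omega, so the frequency ratio is exactly p/q.
locked_train <- function(p, q, omega, n_spikes = 41) {
  period <- 2 * pi / omega
  spike_train(seq(0, by = q * period / p, length.out = n_spikes))
}
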