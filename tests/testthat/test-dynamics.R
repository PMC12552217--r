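test_that("external current follows the sinusoidal protocol", {
  pr <- forcing_protocol("sinusoidal", I0 = 1.5, B = 0.049, omega = 0.007)
  expect_equal(external_current(0, pr), 1.5)
  tt <- seq(0, 2 * pi / 0.007, length.out = 20001)
  expect_equal(min(external_current(tt, pr)), 1.5 * (1 - 0.049),
               tolerance = 1e-6)
  expect_equal(external_current(c(1, 10, 100),
                                forcing_protocol("constant", I0 = 1.5)),
               rep(1.5, 3))
})

test_that("admissible amplitude range keeps the forcing subthreshold", {
  expect_equal(admissible_amplitude_range(1.5, 1.42)[2], 1 - 1.42 / 1.5)
  expect_equal(admissible_amplitude_range(1.5, 1.42)[2], 0.05333,
               tolerance = 1e-4)
  expect_error(admissible_amplitude_range(1.42, 1.42), "empty")
  expect_error(admissible_amplitude_range(1.3, 1.42), "empty")
  # a protocol at B < B_max never drops below I_star
  B <- admissible_amplitude_range(1.5, 1.42)[2] * 0.99
  pr <- forcing_protocol("sinusoidal", I0 = 1.5, B = B, omega = 0.006)
  tt <- seq(0, 3 * 2 * pi / 0.006, length.out = 5000)
  expect_true(all(external_current(tt, pr) > 1.42))
})

test_that("one RK4 step reproduces the scalar closed form on a linear membrane", {
  # with only a unit leak toward V_l = 0 the V-equation is dV/dt = -V
  lin <- hb_params(g_l = 1, V_l = 0, g_d = 1e-300, g_r = 1e-300,
                   g_sd = 1e-300, g_sr = 1e-300)
  pr <- forcing_protocol("constant", I0 = 0)
  for (dt in c(0.5, 0.1, 0.01)) {
    out <- rk4_step(0, hb_state(-60, 0, 0, 0), dt, pr, lin)
    fac <- 1 - dt + dt^2 / 2 - dt^3 / 6 + dt^4 / 24
    expect_equal(out[[1]], -60 * fac, tolerance = 1e-15)
  }
})

test_that("integrator converges at fourth order", {
  pr <- forcing_protocol("constant", I0 = 1.5)
  end_V <- function(dt) {
    cfg <- integration_config(dt = dt, t_transient = 0, t_measure = 100,
                              record_stride = 1)
    hb_integrate(IC2, pr, cfg, hb, record = FALSE)$end_state[[1]]
  }
  # the 0.08/0.04 pair keeps the one-step error well above roundoff
  ref <- end_V(0.001)
  err2 <- abs(end_V(0.08) - ref)
  err1 <- abs(end_V(0.04) - ref)
  expect_gt(err2 / err1, 12)
  expect_lt(err2 / err1, 20)
})

test_that("compiled kernel agrees with the reference R step", {
  pr <- forcing_protocol("sinusoidal", I0 = 1.5, B = 0.049, omega = 0.007)
  n <- 50
  ref <- hbneuron:::hb_integrate_r(IC2, pr, dt = 0.01, n_steps = n,
                                   params = hb)
  cfg <- integration_config(dt = 0.01, t_transient = 0, t_measure = n * 0.01,
                            record_stride = 1)
  tr <- hb_integrate(IC2, pr, cfg, hb)
  expect_equal(tr$V, unname(ref[, "V"]), tolerance = 1e-12)
  expect_equal(tr$a_sr, unname(ref[, "a_sr"]), tolerance = 1e-12)
})

test_that("record length, determinism and restartability contracts hold", {
  pr <- forcing_protocol("sinusoidal", I0 = 1.5, B = 0.0475, omega = 0.006)
  cfg <- integration_config(dt = 0.01, t_transient = 50, t_measure = 200,
                            record_stride = 10)
  tr <- hb_integrate(IC1, pr, cfg, hb)
  expect_length(tr$t, floor(200 / (0.01 * 10)) + 1)
  expect_equal(tr$t[1], 50)  # transient-end sample included
  expect_true(all(diff(tr$t) > 0))
  # bit-identical repeat
  tr2 <- hb_integrate(IC1, pr, cfg, hb)
  expect_identical(tr$V, tr2$V)
  # 0 -> 200 equals 0 -> 100 then restart 100 -> 200, state for state
  c100 <- integration_config(dt = 0.01, t_transient = 0, t_measure = 100,
                             record_stride = 10)
  a <- hb_integrate(IC1, pr, c100, hb)
  # restart must resume the forcing phase at t = 100
  pr2 <- forcing_protocol("sinusoidal", I0 = 1.5, B = 0.0475, omega = 0.006,
                          phase0 = 0.006 * 100)
  b <- hb_integrate(a$end_state, pr2, c100, hb)
  c200 <- integration_config(dt = 0.01, t_transient = 0, t_measure = 200,
                             record_stride = 10)
  full <- hb_integrate(IC1, pr, c200, hb)
  expect_identical(b$end_state[[1]], full$end_state[[1]])
  expect_identical(b$V[length(b$V)], full$V[length(full$V)])
})

test_that("activation variables stay in their invariant ranges along trajectories", {
  pr <- forcing_protocol("sinusoidal", I0 = 1.5, B = 0.0475, omega = 0.00585)
  cfg <- integration_config(dt = 0.01, t_transient = 0, t_measure = 2e4,
                            record_stride = 10)
  for (ic in list(IC1, IC2, IC3)) {
    tr <- hb_integrate(ic, pr, cfg, hb)
    expect_true(all(tr$a_r >= 0 & tr$a_r <= 1))
    expect_true(all(tr$a_sd >= 0 & tr$a_sd <= 1))
    expect_true(all(tr$a_sr >= 0))
    expect_true(all(tr$V > -90 & tr$V < 60))
  }
})

test_that("a trajectory started at the fixed point stays there", {
  fp <- find_fixed_point(I_QUIESCENT, hb)
  pr <- forcing_protocol("constant", I0 = I_QUIESCENT)
  cfg <- integration_config(dt = 0.01, t_transient = 0, t_measure = 1e4,
                            record_stride = 100)
  tr <- hb_integrate(fp, pr, cfg, hb)
  expect_lt(max(abs(tr$V - fp[[1]])), 1e-6)
})

test_that("locking verdicts are invariant to the forcing phase origin", {
  ratios <- vapply(c(0, pi / 2), function(ph) {
    pr <- forcing_protocol("sinusoidal", I0 = 1.5, B = 0.049,
                           omega = 0.00705, phase0 = ph)
    cfg <- integration_config(t_transient = 4e4, t_measure = 8e4)
    tr <- hb_integrate(IC1, pr, cfg, hb, record = FALSE,
                       detect_spikes = TRUE)
    frequency_ratio(spike_train(tr$spike_times), 0.00705)
  }, numeric(1))
  expect_equal(ratios[1], 1, tolerance = 0.01)
  expect_equal(ratios[1], ratios[2], tolerance = 0.01)
})
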