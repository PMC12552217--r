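test_that("threshold crossings are interpolated at the analytic times", {
  tt <- seq(0, 5000, by = 0.1)
  traj <- list(t = tt, V = -60 + 50 * sin(2 * pi * tt / 500))
  st <- detect_spikes(traj, threshold = -20, refractory = 20)
  # upward crossings of -20: sin = 0.8 on the rising flank, period 500 ms
  t0 <- 500 / (2 * pi) * asin(0.8)
  expected <- t0 + 500 * (0:9)
  expect_length(st$times, 10)
  expect_equal(st$times, expected, tolerance = 0.02)
  # constant subthreshold trace has no spikes
  expect_length(detect_spikes(list(t = tt, V = rep(-65, length(tt))))$times, 0)
})

test_that("crossings within the refractory window are merged", {
  tt <- seq(0, 30, by = 0.25)
  bump <- function(c0) 60 * exp(-((tt - c0) / 1.2)^2)
  traj <- list(t = tt, V = -65 + bump(5) + bump(15))
  expect_length(detect_spikes(traj, refractory = 20)$times, 1)
  expect_length(detect_spikes(traj, refractory = 5)$times, 2)
})

test_that("mean firing frequency uses the angular convention", {
  st <- spike_train(seq(0, 10000, by = 1000))
  expect_equal(mean_firing_frequency(st), 2 * pi / 1000)
  expect_true(is.na(mean_firing_frequency(spike_train(numeric(0)))))
  expect_true(is.na(mean_firing_frequency(spike_train(5))))
  # appending exact repetitions leaves the frequency unchanged
  st2 <- spike_train(seq(0, 40000, by = 1000))
  expect_equal(mean_firing_frequency(st2), mean_firing_frequency(st))
})

test_that("frequency ratio is exactly p/q on constructed locked trains", {
  omega <- 0.006283
  for (pq in list(c(2, 1), c(1, 1), c(3, 4), c(2, 3), c(1, 2))) {
    st <- locked_train(pq[1], pq[2], omega)
    expect_equal(frequency_ratio(st, omega), pq[1] / pq[2],
                 tolerance = 1e-12)
  }
  expect_equal(frequency_ratio(spike_train(numeric(0)), omega), 0)
  expect_error(frequency_ratio(locked_train(1, 1, omega), -1), "> 0")
})

test_that("attractor classification separates the three categories", {
  expect_equal(classify_attractor(numeric(0))$category, "subthreshold")
  lab <- classify_attractor(rep(c(800, 1200), 10))
  expect_equal(lab$category, "periodic")
  expect_equal(lab$period_k, 2L)
  expect_equal(classify_attractor(rep(1000, 12))$period_k, 1L)
  lab3 <- classify_attractor(rep(c(200, 300, 900), 8))
  expect_equal(lab3$period_k, 3L)
  # jitter below the tolerance keeps the periodic verdict
  fx <- make_fixture("isi_periodic", pattern = c(800, 1200), n_repeats = 12,
                     jitter = 0.002, seed = 42)
  expect_equal(classify_attractor(fx$isi)$category, "periodic")
  # aperiodic logistic-map surrogate is chaotic
  ch <- make_fixture("isi_chaotic_surrogate", n = 60)
  expect_equal(classify_attractor(ch$isi)$category, "chaotic")
  expect_equal(classify_attractor(c(900, 1100))$category, "undetermined")
  expect_error(classify_attractor(c(-1, 500)), "positive")
})

test_that("classification is invariant to rotation, rescaling and window doubling", {
  isi <- rep(c(700, 900, 1400), 8)
  base <- classify_attractor(isi)
  rot <- classify_attractor(isi[c(5:length(isi), 1:4)])
  expect_equal(rot$category, base$category)
  expect_equal(rot$period_k, base$period_k)
  scl <- classify_attractor(3.7 * isi)
  expect_equal(scl$period_k, base$period_k)
  dbl <- classify_attractor(rep(c(700, 900, 1400), 16))
  expect_equal(dbl$period_k, base$period_k)
  ch <- make_fixture("isi_chaotic_surrogate", n = 60)$isi
  expect_equal(classify_attractor(2 * ch)$category,
               classify_attractor(ch)$category)
})

test_that("an ISI scan inside the 1:1 plateau is clean and deterministic", {
  om <- c(0.00710, 0.00715)
  cfg <- integration_config(t_transient = 3e4, t_measure = 6e4)
  sc <- isi_bifurcation_scan(om, B = 0.049, ic = IC1, params = hb,
                             config = cfg)
  expect_equal(sc$labels$category, rep("periodic", 2))
  expect_equal(sc$labels$period_k, rep(1L, 2))
  expect_equal(sc$labels$ratio, rep(1, 2), tolerance = 5e-3)
  # one ISI cluster per omega on the plateau
  for (o in om) {
    isi <- sc$isi$isi[sc$isi$omega == o]
    expect_lt(diff(range(isi)) / mean(isi), 0.01)
  }
  sc2 <- isi_bifurcation_scan(om, B = 0.049, ic = IC1, params = hb,
                              config = cfg)
  expect_identical(sc$isi$isi, sc2$isi$isi)
})
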