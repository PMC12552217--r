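test_that("uncertain fraction matches the closed form on a stripe basin", {
  fx <- make_fixture("basin_stripes", w = 0.1)
  eps <- c(0.01, 0.025, 0.05, 0.1)
  f <- uncertain_fraction(fx$label_fun, eps, xlim = c(0, 1), ylim = c(0, 1),
                          n = c(1001, 5))
  expect_equal(f, fx$f_expected(eps), tolerance = 0.01)
  expect_true(all(f >= 0 & f <= 1))
  # a region strictly inside one stripe is certain at small epsilon
  f0 <- uncertain_fraction(fx$label_fun, c(0.005, 0.01),
                           xlim = c(0.01, 0.08), ylim = c(0, 1),
                           n = c(201, 3))
  expect_equal(f0, c(0, 0))
})

test_that("uncertainty exponent recovers noiseless power laws exactly", {
  fx <- make_fixture("basin_power_law", alpha = 0.7, c0 = 0.3)
  est <- uncertainty_exponent(fx$epsilons, fx$f_values)
  expect_equal(est$alpha, 0.7, tolerance = 1e-10)
  expect_equal(est$dim, 1.3, tolerance = 1e-10)
  expect_equal(est$D - est$alpha, est$dim)
  expect_gt(est$r_squared, 1 - 1e-12)
  # zero fractions are excluded with a warning; too few pairs error out
  expect_warning(
    est2 <- uncertainty_exponent(c(fx$epsilons, 1e-6),
                                 c(fx$f_values, 0)),
    "excluded")
  expect_equal(est2$alpha, 0.7, tolerance = 1e-10)
  expect_error(
    suppressWarnings(uncertainty_exponent(c(1e-3, 1e-2, 1e-1),
                                          c(0, 0, 0.5))),
    "at least 3")
})

test_that("a smooth boundary has exponent near 1, a random basin near 0", {
  # half-plane boundary: f(eps) is linear in eps
  smooth_lab <- function(x, y) if (x < 0.5) "A" else "B"
  eps <- 10^seq(-2.5, -1.2, length.out = 6)
  f <- uncertain_fraction(smooth_lab, eps, xlim = c(0, 1), ylim = c(0, 1),
                          n = c(2001, 5))
  est <- uncertainty_exponent(eps, f)
  expect_equal(est$alpha, 1, tolerance = 0.05)
  expect_equal(est$dim, 1, tolerance = 0.05)
  # fully scrambled labels: f is flat in eps, alpha near 0
  set.seed(99)
  rnd <- structure(list(x = seq(0, 1, length.out = 201),
                        y = seq(0, 1, length.out = 41),
                        labels = matrix(sample(c("A", "B"), 201 * 41,
                                               replace = TRUE), 201, 41),
                        spec = NULL),
                   class = "basin_map")
  fr <- uncertain_fraction(rnd, c(1, 2, 4, 8) * (1 / 200))
  estr <- uncertainty_exponent(c(1, 2, 4, 8) * (1 / 200), fr)
  expect_lt(abs(estr$alpha), 0.1)
})

test_that("basin maps label every cell and are resolution-consistent", {
  spec <- basin_spec("asr_asd", xlim = c(0.11, 0.145), ylim = c(0, 0.05),
                     nx = 17, ny = 17, omega = 0.006, B = 0.0475)
  bm <- compute_basin(spec, hb)
  expect_true(all(bm$labels %in% c("subthreshold", "periodic", "chaotic",
                                   "undetermined")))
  expect_equal(dim(bm$labels), c(17L, 17L))
  expect_lt(mean(bm$labels == "undetermined"), 0.05)
  # all three coexisting attractors appear in this region
  expect_true(all(c("subthreshold", "periodic", "chaotic") %in% bm$labels))
  # area fractions from the 2x-coarser subgrid agree within 5 points
  fine <- table(factor(bm$labels,
                       c("subthreshold", "periodic", "chaotic"))) / 17^2
  sub <- bm$labels[seq(1, 17, by = 2), seq(1, 17, by = 2)]
  coarse <- table(factor(sub, c("subthreshold", "periodic", "chaotic"))) / 9^2
  expect_lt(max(abs(fine - coarse)), 0.05)
})

test_that("basin cells reproduce the canonical coexisting attractors", {
  # at omega = 0.006, B = 0.0475: IC1 chaotic, IC2 subthreshold
  spec <- basin_spec("asr_asd", xlim = c(0.2, 0.5), ylim = c(0, 0.01),
                     nx = 2, ny = 2, omega = 0.006, B = 0.0475)
  cfg <- integration_config(dt = 0.01, t_transient = 3e4, t_measure = 6e4)
  bm <- compute_basin(spec, hb, config = cfg)
  # x = a_sr0 in {0.2, 0.5}, y = a_sd0 = 0 row: IC2 and IC1
  expect_equal(bm$labels[1, 1], "subthreshold")
  expect_equal(bm$labels[2, 1], "chaotic")
})

test_that("the Benettin exponent matches the linearization at a stable focus", {
  pr <- forcing_protocol("constant", I0 = I_QUIESCENT)
  ly <- max_lyapunov(IC2, pr, hb, t_transient = 3e4, t_accum = 2e5)
  lead <- Re(linearized_eigenvalues(I_QUIESCENT, hb)[1])
  expect_lt(ly$lambda, 0)
  expect_equal(ly$lambda, lead, tolerance = 0.05)
  # the running estimate has settled
  n <- length(ly$trace)
  expect_lt(abs(ly$trace[n] - ly$trace[floor(n / 2)]), 5e-5)
})
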