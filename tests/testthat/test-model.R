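test_that("temperature factors follow Q10 scaling and compose multiplicatively", {
  tf <- temperature_factors(25, 25)
  expect_identical(c(tf$rho, tf$phi), c(1, 1))
  tf <- temperature_factors(35, 25)
  expect_equal(c(tf$rho, tf$phi), c(1.3, 3.0))
  # direct evaluation of the powers at the default temperature
  tf <- temperature_factors(18, 25)
  expect_equal(tf$rho, 1.3^(-0.7), tolerance = 1e-15)
  expect_equal(tf$phi, 3.0^(-0.7), tolerance = 1e-15)
  expect_equal(tf$rho, 0.8322, tolerance = 1e-4)
  expect_equal(tf$phi, 0.4635, tolerance = 1e-4)
  # rho(T1 -> T2) * rho(T2 -> T3) = rho(T1 -> T3)
  set.seed(11)
  for (i in 1:20) {
    Ts <- runif(3, 0, 40)
    a <- temperature_factors(Ts[2], Ts[1])
    b <- temperature_factors(Ts[3], Ts[2])
    ab <- temperature_factors(Ts[3], Ts[1])
    expect_equal(a$rho * b$rho, ab$rho, tolerance = 1e-12)
    expect_equal(a$phi * b$phi, ab$phi, tolerance = 1e-12)
  }
  expect_error(temperature_factors(NaN, 25), "finite")
})

test_that("steady-state activation is a bounded increasing sigmoid", {
  for (ch in c("d", "r", "sd")) {
    V0 <- hb[[paste0("V0_", ch)]]
    expect_equal(steady_state_activation(V0, ch, hb), 0.5)
    expect_equal(steady_state_activation(1e4, ch, hb), 1)
    expect_equal(steady_state_activation(-1e4, ch, hb), 0)
    V <- sort(runif(200, -120, 40))
    a <- steady_state_activation(V, ch, hb)
    expect_true(all(a > 0 & a < 1))
    expect_true(all(diff(a) > 0))
  }
  # scalar evaluation: s_sd = 0.09, V0_sd = -40 at V = -65
  expect_equal(steady_state_activation(-65, "sd", hb),
               1 / (1 + exp(2.25)), tolerance = 1e-15)
  expect_equal(steady_state_activation(-65, "sd", hb), 0.0953,
               tolerance = 1e-3)
  expect_error(steady_state_activation(-65, "sr", hb))
})

test_that("ionic and leak currents follow the driving-force law", {
  for (ch in c("d", "r", "sd", "sr")) {
    Vx <- hb[[paste0("V_", ch)]]
    expect_equal(ionic_current(ch, Vx, 0.4, hb), 0)
    expect_equal(ionic_current(ch, -55, 0, hb), 0)
  }
  a <- steady_state_activation(-65, "sd", hb)
  expect_equal(ionic_current("sd", -65, a, hb),
               hb$rho * 0.25 * a * (-65 - 50), tolerance = 1e-15)
  expect_equal(ionic_current("sd", -65, a, hb), -2.28, tolerance = 5e-3)
  expect_error(ionic_current("sd", -65, -0.1, hb), ">= 0")
  expect_equal(leak_current(-60, hb), 0)
  expect_equal(leak_current(-50, hb), 1.0)
  V <- runif(50, -90, 0)
  expect_true(all(sign(leak_current(V, hb)) == sign(V - hb$V_l)))
})

test_that("vector field has the correct equilibrium structure and signs", {
  V <- -55
  st <- hb_state(V, steady_state_activation(V, "r", hb), 0.2, 0.1)
  d <- hb_vector_field(0, st, 1.5, hb)
  expect_equal(d[["a_r"]], 0)
  # a_sd below its sigmoid relaxes upward
  st2 <- hb_state(V, 0.1, steady_state_activation(V, "sd", hb) - 0.2, 0.1)
  expect_gt(hb_vector_field(0, st2, 1.5, hb)[["a_sd"]], 0)
  expect_error(hb_vector_field(0, c(NaN, 0, 0, 0), 1.5, hb), "finite")
})

test_that("fixed point solves the reduced 1-D problem found by brute force", {
  fp <- find_fixed_point(1.5, hb)
  res <- hb_vector_field(0, fp, 1.5, hb)
  expect_lt(max(abs(res)), 1e-9)
  # current balance: sum of membrane currents equals -I_ext
  tot <- leak_current(fp[[1]], hb) +
    ionic_current("d", fp[[1]], steady_state_activation(fp[[1]], "d", hb), hb) +
    ionic_current("r", fp[[1]], fp[[2]], hb) +
    ionic_current("sd", fp[[1]], fp[[3]], hb) +
    ionic_current("sr", fp[[1]], fp[[4]], hb)
  expect_equal(tot, -1.5, tolerance = 1e-10)
  # independent oracle: dense scan of the reduced equation in V
  Vg <- seq(-90, -30, by = 0.005)
  rg <- vapply(Vg, hbneuron:::fixed_point_residual_V, numeric(1),
               i_ext = 1.5, params = hb)
  i <- which(rg[-1] * rg[-length(rg)] <= 0)[1]
  expect_lt(abs(fp[[1]] - Vg[i]), 0.01)
  expect_gt(fp[[1]], -70)
  expect_lt(fp[[1]], -60)
  # residual property across the quiescent current range
  for (I in seq(1.43, 2.0, by = 0.05)) {
    r <- hb_vector_field(0, find_fixed_point(I, hb), I, hb)
    expect_lt(max(abs(r)), 1e-9)
  }
  expect_error(find_fixed_point(1.5, hb, interval = c(-90, -80)),
               "no equilibrium")
})

test_that("analytic Jacobian matches central finite differences", {
  fp <- find_fixed_point(1.5, hb)
  J <- hb_jacobian(fp, hb)
  h <- 1e-6
  Jfd <- matrix(0, 4, 4)
  x0 <- as.numeric(fp)
  for (j in 1:4) {
    ep <- em <- x0
    ep[j] <- ep[j] + h
    em[j] <- em[j] - h
    Jfd[, j] <- (hb_vector_field(0, ep, 1.5, hb) -
                   hb_vector_field(0, em, 1.5, hb)) / (2 * h)
  }
  expect_equal(unname(J), Jfd, tolerance = 1e-6)
  ev <- eigen(J, only.values = TRUE)$values
  evfd <- eigen(Jfd, only.values = TRUE)$values
  expect_equal(sort(Mod(ev)), sort(Mod(evfd)), tolerance = 1e-6)
})

test_that("leading eigenvalue pair crosses the imaginary axis inside [1.40, 1.42]", {
  ev <- linearized_eigenvalues(1.5, hb)
  expect_lt(Re(ev[1]), 0)
  expect_gt(abs(Im(ev[1])), 0)
  expect_equal(Re(ev[1]), Re(Conj(ev[2])))
  # below the Hopf point the focus is unstable
  expect_gt(Re(linearized_eigenvalues(1.40, hb)[1]), 0)
  expect_lt(Re(linearized_eigenvalues(1.42, hb)[1]), 0)
})
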