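test_that("activation is 0 in diastole, 1 at peak, smooth and periodic", {
  timing <- list(onset = 0, duration = 0.4)
  T_c <- 0.8
  # exactly zero at onset, negligible through late diastole
  expect_equal(lpm_activation(0, timing, T_c), 0)
  late <- seq(0.45, 0.75, by = 0.01)
  expect_true(all(lpm_activation(late, timing, T_c) < 1e-3))
  # normalized: the maximum over the cycle is 1
  tt <- seq(0, T_c, length.out = 4001)
  e <- lpm_activation(tt, timing, T_c)
  expect_equal(max(e), 1, tolerance = 1e-6)
  expect_true(all(e >= 0 & e <= 1 + 1e-12))
  # periodic with the cycle
  expect_equal(lpm_activation(0.1, timing, T_c),
               lpm_activation(0.1 + 3 * T_c, timing, T_c))
  # onset shifts the waveform rigidly
  sh <- list(onset = 0.25, duration = 0.4)
  expect_equal(lpm_activation(0.25 * T_c + 0.07, sh, T_c),
               lpm_activation(0.07, timing, T_c))
})

test_that("activation cycle integral matches independent quadrature", {
  timing <- list(onset = 0, duration = 0.4)
  T_c <- 0.8
  oracle <- stats::integrate(function(t) lpm_activation(t, timing, T_c),
                             0, T_c, subdivisions = 400L,
                             rel.tol = 1e-10)$value
  tt <- seq(0, T_c, length.out = 20001)[-20001]
  riemann <- mean(lpm_activation(tt, timing, T_c)) * T_c
  expect_equal(riemann, oracle, tolerance = 1e-5)
})

test_that("invalid activation timing is rejected", {
  expect_error(lpm_activation(0.1, list(onset = -0.1, duration = 0.4), 0.8),
               "timing")
  expect_error(lpm_activation(0.1, list(onset = 0, duration = 1.4), 0.8),
               "timing")
  expect_error(chamber_params(Ees = 1, V0_es = 10, V0_ed = 5,
                              edpvr_A = 0.3, edpvr_B = 0.03,
                              activation = list(onset = 2, duration = 0.4)),
               "activation")
})

test_that("chamber pressure interpolates EDPVR and ESPVR laws", {
  T_c <- 0.8
  ch <- chamber_params(Ees = 0.5, V0_es = 50, V0_ed = 40,
                       edpvr_A = 0.3, edpvr_B = 0.03,
                       espvr_shape = "linear",
                       activation = list(onset = 0, duration = 0.4))
  # full diastole: EDPVR passes through its unstressed volume
  t_dias <- 0.6
  expect_equal(lpm_chamber_pressure(40, t_dias, ch, T_c), 0,
               tolerance = 1e-6)
  # peak activation: linear ESPVR intercept and slope
  tt <- seq(0, T_c, length.out = 8001)
  t_peak <- tt[which.max(lpm_activation(tt, ch$activation, T_c))]
  expect_equal(lpm_chamber_pressure(50, t_peak, ch, T_c), 0,
               tolerance = 1e-4)
  # Ees 0.5 mmHg/ml, 10 ml above V0_es -> 5 mmHg under the linear law
  expect_equal(lpm_chamber_pressure(60, t_peak, ch, T_c), 5,
               tolerance = 0.01)
  expect_error(lpm_chamber_pressure(-1, 0, ch, T_c))
})

test_that("valve law is a diode: no reverse flow, dp/R when open", {
  v <- valve_params(0.05)
  expect_equal(lpm_valve_flow(-5, v), 0)
  expect_equal(lpm_valve_flow(0, v), 0)
  expect_equal(lpm_valve_flow(10, v), 200)       # dp/R oracle
  expect_equal(lpm_valve_flow(10, v, state = 0.5), 100)
  expect_equal(lpm_valve_flow(-10, v, state = 1), 0)
  expect_true(all(lpm_valve_flow(seq(-20, 20, by = 0.5), v) >= 0))
})

test_that("pump head law: shutoff, omega^2 monotonicity, decreasing in Q", {
  pm <- pump_params(speed = 5400, coeff_q2 = -0.010928, coeff_w2 = 4.589e-4)
  omega <- 5400 * 2 * pi / 60
  expect_equal(lpm_pump_head(0, pm), 4.589e-4 * omega^2)
  # consistency with an independent polynomial evaluation
  Q <- seq(0, 150, by = 5)
  indep <- vapply(Q, function(q) {
    sum(c(pm$coeff_q2, pm$coeff_q1, pm$coeff_w2) * c(q^2, q, omega^2))
  }, numeric(1))
  expect_equal(lpm_pump_head(Q, pm), indep)
  # non-increasing in flow at fixed speed
  expect_true(all(diff(lpm_pump_head(Q, pm)) <= 0))
  # strictly larger head at higher speed, equal flow
  slow <- pump_params(speed = 4300, coeff_q2 = -0.010928,
                      coeff_w2 = 4.589e-4)
  expect_true(all(lpm_pump_head(Q, pm) > lpm_pump_head(Q, slow)))
  expect_warning(lpm_pump_head(500, pm, warn = TRUE), "extrapolat")
  expect_error(pump_params(speed = 5000, coeff_q2 = 0.01, coeff_w2 = 1e-4))
})

test_that("closed-loop derivatives conserve total blood volume", {
  p <- lpm_params()
  y0 <- rvadflow:::.lpm_initial_state(p)
  set.seed(42)
  for (i in 1:20) {
    y <- y0 * runif(length(y0), 0.85, 1.15)
    dy <- lpm_rhs(runif(1, 0, 0.8), y, p)
    expect_equal(sum(dy[1:8]), 0, tolerance = 1e-9 * max(abs(dy)))
  }
  ybad <- y0
  ybad[3] <- NaN
  expect_error(lpm_rhs(0.1, ybad, p), "non-finite")
})

test_that("RK4 reproduces the analytic RC discharge to < 0.1%", {
  # two compartments (C1, C2) exchanging through R: pressure difference
  # decays as exp(-t/tau), tau = R / (1/C1 + 1/C2)
  R <- 0.1; C1 <- 2; C2 <- 5
  f <- function(t, y) {
    q <- ((y[1] / C1) - (y[2] / C2)) / R
    c(-q, q)
  }
  y0 <- c(10, 0)
  sol <- rk4_integrate(f, y0, 0, 0.5, dt = 2e-4, save_every = 50)
  tau <- R / (1 / C1 + 1 / C2)
  dp0 <- y0[1] / C1 - y0[2] / C2
  dp <- sol$state[, 1] / C1 - sol$state[, 2] / C2
  expect_equal(dp, dp0 * exp(-sol$time / tau), tolerance = 1e-3)
})

test_that("fast integrator agrees with the reference right-hand side", {
  p <- lpm_params()
  fast <- rvadflow:::.lpm_run_fast(p, n_cycles = 1, dt = 1e-3,
                                   save_every = 10)
  ref <- rk4_integrate(function(t, y) lpm_rhs(t, y, p),
                       rvadflow:::.lpm_initial_state(p), 0, 0.8,
                       dt = 1e-3, save_every = 10)
  expect_equal(unname(fast$state), unname(ref$state), tolerance = 1e-10)
})

test_that("parameter validation enforces the structural invariants", {
  expect_error(lpm_params(vessels = list(sv = list(L = 0.1))), "inertance")
  expect_error(lpm_params(chambers = list(la = list(espvr_shape =
                                                      "curvilinear"))),
               "linear")
  p <- lpm_params()
  expect_s3_class(p, "lpm_params")
  expect_identical(p$chambers$lv$Ees, 0.86)
  expect_identical(p$chambers$rv$Ees, 0.5)
  expect_identical(p$pumps$lvad$speed, 5400)
  expect_identical(p$pumps$rvad$speed, 4300)
  h <- lpm_params("healthy")
  expect_identical(h$chambers$lv$Ees, 3.54)
  expect_identical(h$chambers$rv$Ees, 1.75)
})
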