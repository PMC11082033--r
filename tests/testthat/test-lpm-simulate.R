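test_that("closed loop conserves volume and reaches periodicity", {
  traj <- default_bivad_traj()
  expect_lt(abs(traj$volume_drift), 1e-3)          # < 0.1 % over the run
  resid <- stats::na.omit(traj$periodicity)
  expect_lt(utils::tail(resid, 1), 1e-3)
  # residual shrinks as the loop settles (compare early vs late cycles)
  expect_lt(mean(utils::tail(resid, 3)), mean(resid[1:3]))
})

test_that("BiVAD support keeps the pulmonary valve closed all cycle", {
  s <- default_bivad_summary()
  expect_equal(s$pulmonary_valve_open_fraction, 0)
  expect_equal(s$aortic_valve_open_fraction, 0)
})

test_that("healthy baseline without pumps ejects through both valves", {
  traj <- suppressWarnings(
    lpm_simulate(lpm_params("healthy"), n_cycles = 10, dt = 5e-4))
  s <- lpm_summarize(traj)
  expect_gt(s$aortic_valve_open_fraction, 0.1)
  expect_gt(s$pulmonary_valve_open_fraction, 0.1)
  expect_gt(s$cardiac_output, 2)
  expect_equal(s$pump_flow_lvad, 0, tolerance = 1e-6)
})

test_that("summary resistances are identities of the summary's own means", {
  s <- default_bivad_summary()
  co_mls <- s$cardiac_output * 1000 / 60
  expect_identical(s$SVR, (s$MAP - s$RAP) / co_mls)
  expect_identical(s$PVR, (s$mPAP - s$LAP) / co_mls)
  expect_equal(s$heart_rate, 75)
})

test_that("summary of a constant trajectory returns the constants", {
  traj <- default_bivad_traj()
  fake <- traj
  n <- length(traj$time)
  fake$state <- matrix(rep(traj$state[n, ], each = n), nrow = n,
                       dimnames = dimnames(traj$state))
  fake$aux <- matrix(rep(traj$aux[n, ], each = n), nrow = n,
                     dimnames = dimnames(traj$aux))
  s <- lpm_summarize(fake)
  expect_equal(s$MAP, unname(traj$aux[n, "P_sa"]))
  expect_equal(s$RAP, unname(traj$aux[n, "P_ra"]))
  expect_equal(s$cardiac_output,
               unname(traj$state[n, "Q_sys"]) * 60 / 1000)
  expect_equal(s$stroke_volume_RV, 0)
})

test_that("physiology responds monotonically to Ees and pump speed", {
  s0 <- default_bivad_summary()
  weaker <- suppressWarnings(lpm_simulate(
    lpm_params(chambers = list(rv = list(Ees = 0.35))),
    n_cycles = 15, dt = 5e-4))
  expect_lte(lpm_summarize(weaker)$ejection_fraction_RV,
             s0$ejection_fraction_RV + 0.05)
  faster <- suppressWarnings(lpm_simulate(
    lpm_params(pumps = list(rvad = list(speed = 4800))),
    n_cycles = 15, dt = 5e-4))
  expect_gte(lpm_summarize(faster)$pump_flow_rvad,
             s0$pump_flow_rvad - 0.01)
})

test_that("tricuspid inflow is non-negative with E and A peaks", {
  traj <- default_bivad_traj()
  w <- lpm_export_waveforms(traj)
  expect_equal(attr(w, "T_cycle"), 0.8)            # 75 bpm
  expect_true(all(diff(w$time_s) > 0))
  expect_equal(diff(range(diff(w$time_s))), 0, tolerance = 1e-9)
  expect_true(all(w$tricuspid_inflow_ml_s >= 0))
  expect_identical(count_peaks(w$tricuspid_inflow_ml_s), 2L)
})

test_that("exported waveforms are consistent with the cycle summary", {
  traj <- default_bivad_traj()
  w <- lpm_export_waveforms(traj)
  s <- default_bivad_summary()
  sv_w <- max(w$rv_volume_ml) - min(w$rv_volume_ml)
  expect_equal(sv_w, s$stroke_volume_RV, tolerance = 1e-9)
  # cycle inflow equals cycle outflow within 1 %
  inflow <- sum(w$tricuspid_inflow_ml_s) * traj$save_dt
  rows <- rvadflow:::.last_cycle_rows(traj)
  outflow <- sum(traj$state[rows, "Q_rvad"] + traj$aux[rows, "Q_pu"]) *
    traj$save_dt
  expect_equal(inflow, outflow, tolerance = 0.01)
})

test_that("waveform CSV and summary JSON round-trip", {
  traj <- default_bivad_traj()
  w <- lpm_export_waveforms(traj)
  tmp <- tempfile(fileext = ".csv")
  lpm_write_waveforms(w, tmp)
  w2 <- lpm_read_waveforms(tmp)
  expect_equal(w2$tricuspid_inflow_ml_s, w$tricuspid_inflow_ml_s)
  expect_equal(attr(w2, "T_cycle"), attr(w, "T_cycle"), tolerance = 1e-9)

  s <- default_bivad_summary()
  js <- tempfile(fileext = ".json")
  lpm_write_summary(s, js)
  payload <- jsonlite::read_json(js)
  expect_equal(payload[["Cardiac output (L/min)"]], s$cardiac_output)
  expect_equal(payload[["Systemic vascular resistance (mmHg.s.mL-1)"]],
               s$SVR)
})

test_that("the shipped YAML configuration reproduces the preset", {
  cfg <- system.file("extdata", "bivad_failure.yaml", package = "rvadflow")
  expect_true(nzchar(cfg))
  p <- lpm_read_config(cfg)
  q <- lpm_params()
  expect_equal(p$chambers$rv$edpvr_B, q$chambers$rv$edpvr_B)
  expect_equal(p$pumps$lvad$coeff_w2, q$pumps$lvad$coeff_w2)
  expect_equal(p$vessels$sa$R, q$vessels$sa$R)
  expect_equal(p$heart_rate, q$heart_rate)
})

test_that("adaptive integration agrees with the fixed-step run", {
  p <- lpm_params()
  # two cycles are enough to compare integrators (periodicity warning is
  # expected and irrelevant here)
  fixed <- suppressWarnings(lpm_simulate(p, n_cycles = 2, dt = 2e-4))
  adaptive <- suppressWarnings(
    lpm_simulate(p, n_cycles = 2, dt = 2e-4, method = "lsoda"))
  i <- length(fixed$time)
  expect_equal(unname(fixed$state[i, "V_rv"]),
               unname(adaptive$state[i, "V_rv"]), tolerance = 5e-3)
})
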