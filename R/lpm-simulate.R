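#' Fixed-step RK4 integration
#'
#' Minimal classical Runge--Kutta integrator with uniform step and thinned
#' storage. Used by [lpm_simulate()] and exported so small sub-circuits
#' (e.g. an isolated RC discharge) can be integrated with the identical
#' scheme for verification.
#'
#' @param f Function `f(t, y, ...)` returning `dy/dt`.
#' @param y0 Initial state (named vector).
#' @param t0,t_end Integration window, s.
#' @param dt Step size, s.
#' @param save_every Store every `save_every`-th step (the initial state is
#'   always stored).
#' @param ... Passed on to `f`.
#' @return List with `time` (vector) and `state` (matrix, one row per saved
#'   time).
#' @export
rk4_integrate <- function(f, y0, t0, t_end, dt, save_every = 1L, ...) {
  stopifnot(dt > 0, t_end > t0, save_every >= 1)
  n_steps <- ceiling((t_end - t0) / dt - 1e-9)
  n_save <- floor(n_steps / save_every) + 1L
  out <- matrix(NA_real_, n_save, length(y0),
                dimnames = list(NULL, names(y0)))
  times <- numeric(n_save)
  y <- y0
  out[1L, ] <- y
  times[1L] <- t0
  row <- 1L
  t <- t0
  half <- dt / 2
  for (i in seq_len(n_steps)) {
    k1 <- f(t, y, ...)
    k2 <- f(t + half, y + half * k1, ...)
    k3 <- f(t + half, y + half * k2, ...)
    k4 <- f(t + dt, y + dt * k3, ...)
    y <- y + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t0 + i * dt
    if (i %% save_every == 0L) {
      row <- row + 1L
      out[row, ] <- y
      times[row] <- t
    }
  }
  list(time = times[seq_len(row)], state = out[seq_len(row), , drop = FALSE])
}

#' Integrate the closed loop to periodic steady state
#'
#' Runs the circulation model for `n_cycles` cardiac cycles with a
#' fixed-step RK4 scheme (default step 0.0002 s) or, optionally, an
#' adaptive stiff solver. The trajectory is thinned to `save_dt` for
#' storage; instantaneous pressures and flows are reconstructed at the
#' saved times. A periodicity residual (maximum relative change of
#' cycle-mean volumes between consecutive cycles) and the total-volume
#' drift are attached as convergence diagnostics.
#'
#' @param params An [lpm_params()] object.
#' @param n_cycles Number of cardiac cycles to integrate.
#' @param dt Integrator step, s.
#' @param save_dt Output sampling interval, s (rounded to a multiple of
#'   `dt`).
#' @param method `"rk4"` (fixed step) or `"lsoda"` (adaptive, via deSolve).
#' @return An object of class `lpm_trajectory`: list with `time`, `state`
#'   (volumes and inertial flows), `aux` (pressures and valve flows),
#'   `params`, `T_cycle`, `periodicity` (residual per cycle pair) and
#'   `volume_drift` (relative).
#' @export
lpm_simulate <- function(params, n_cycles = 30, dt = 2e-4, save_dt = 2e-3,
                         method = c("rk4", "lsoda")) {
  method <- match.arg(method)
  validate_lpm_params(params)
  stopifnot(dt > 0, n_cycles >= 1)
  T_cycle <- 60 / params$heart_rate
  t_end <- n_cycles * T_cycle
  y0 <- .lpm_initial_state(params)

  if (method == "rk4") {
    save_every <- max(1L, round(save_dt / dt))
    sol <- .lpm_run_fast(params, n_cycles, dt, save_every)
    time <- sol$time
    state <- sol$state
  } else {
    time <- seq(0, t_end, by = save_dt)
    des <- deSolve::ode(y = y0, times = time,
                        func = function(t, y, parms) list(lpm_rhs(t, y, parms)),
                        parms = params, method = "lsoda",
                        rtol = 1e-8, atol = 1e-8)
    state <- unname(des[, -1, drop = FALSE])
    colnames(state) <- names(y0)
  }

  aux <- .lpm_aux(time, state, params)

  vol_cols <- 1:8
  total <- rowSums(state[, vol_cols, drop = FALSE])
  volume_drift <- (total[length(total)] - total[1]) / total[1]

  cycle_id <- pmin(floor(time / T_cycle) + 1L, n_cycles)
  cyc_means <- apply(state[, vol_cols, drop = FALSE], 2,
                     function(v) tapply(v, cycle_id, mean))
  if (n_cycles > 1) {
    d <- abs(diff(as.matrix(cyc_means)))
    scale <- pmax(abs(as.matrix(cyc_means)[-1, , drop = FALSE]), 1)
    periodicity <- apply(d / scale, 1, max)
  } else {
    periodicity <- NA_real_
  }

  res <- structure(list(time = time, state = state, aux = aux,
                        params = params, T_cycle = T_cycle,
                        n_cycles = n_cycles, dt = dt, save_dt = save_dt,
                        periodicity = periodicity,
                        volume_drift = volume_drift),
                   class = "lpm_trajectory")
  last_res <- utils::tail(stats::na.omit(periodicity), 1)
  if (length(last_res) && last_res > 1e-3) {
    warning(sprintf(
      "periodic steady state not reached in %d cycles (residual %.2e)",
      n_cycles, last_res))
  }
  res
}

# rows of the final full cycle of a trajectory
.last_cycle_rows <- function(traj) {
  t_end <- traj$time[length(traj$time)]
  which(traj$time > t_end - traj$T_cycle + 1e-9 & traj$time <= t_end + 1e-9)
}

#' Cycle-averaged hemodynamic summary
#'
#' Averages the final cycle of a periodic trajectory into the standard
#' clinical indices: cardiac output, mean arterial / pulmonary arterial /
#' atrial pressures, systemic and pulmonary vascular resistance
#' (recomputed from the summary's own means, `SVR = (MAP - RAP) / CO`,
#' `PVR = (mPAP - LAP) / CO` with CO in ml/s), RV stroke volume
#' (max - min RV volume) and RV ejection fraction (SV/EDV).
#'
#' @param traj An `lpm_trajectory`.
#' @return Object of class `hemodynamic_summary` (a named list). If the
#'   trajectory had not converged to periodicity, a
#'   `"periodicity_warning"` attribute carries the residual.
#' @export
lpm_summarize <- function(traj) {
  stopifnot(inherits(traj, "lpm_trajectory"))
  rows <- .last_cycle_rows(traj)
  st <- traj$state[rows, , drop = FALSE]
  ax <- traj$aux[rows, , drop = FALSE]

  MAP  <- mean(ax[, "P_sa"]); RAP <- mean(ax[, "P_ra"])
  mPAP <- mean(ax[, "P_pa"]); LAP <- mean(ax[, "P_la"])
  CO_mls <- mean(st[, "Q_sys"])         # systemic flow = total output
  SV <- max(st[, "V_rv"]) - min(st[, "V_rv"])
  EDV <- max(st[, "V_rv"])

  out <- structure(list(
    heart_rate = traj$params$heart_rate,
    cardiac_output = CO_mls * 60 / 1000,
    MAP = MAP, mPAP = mPAP, LAP = LAP, RAP = RAP,
    SVR = (MAP - RAP) / CO_mls,
    PVR = (mPAP - LAP) / CO_mls,
    stroke_volume_RV = SV,
    ejection_fraction_RV = 100 * SV / EDV,
    pump_flow_lvad = mean(st[, "Q_lvad"]) * 60 / 1000,
    pump_flow_rvad = mean(st[, "Q_rvad"]) * 60 / 1000,
    pulmonary_valve_open_fraction = mean(ax[, "Q_pu"] > 0),
    aortic_valve_open_fraction = mean(ax[, "Q_ao"] > 0)
  ), class = "hemodynamic_summary")
  last_res <- utils::tail(stats::na.omit(traj$periodicity), 1)
  if (length(last_res) && last_res > 1e-3) {
    attr(out, "periodicity_warning") <- last_res
  }
  out
}

#' @export
print.hemodynamic_summary <- function(x, ...) {
  cat("Cycle-averaged hemodynamics\n")
  cat(sprintf("  Heart rate            %6.1f bpm\n", x$heart_rate))
  cat(sprintf("  Cardiac output        %6.2f L/min\n", x$cardiac_output))
  cat(sprintf("  MAP / mPAP            %6.1f / %.1f mmHg\n", x$MAP, x$mPAP))
  cat(sprintf("  LAP / RAP             %6.1f / %.1f mmHg\n", x$LAP, x$RAP))
  cat(sprintf("  SVR / PVR             %6.3f / %.3f mmHg.s/ml\n",
              x$SVR, x$PVR))
  cat(sprintf("  RV SV / EF            %6.1f ml / %.1f %%\n",
              x$stroke_volume_RV, x$ejection_fraction_RV))
  cat(sprintf("  Pump flow L / R       %6.2f / %.2f L/min\n",
              x$pump_flow_lvad, x$pump_flow_rvad))
  invisible(x)
}

#' Export one-cycle boundary waveforms
#'
#' Extracts the final cycle's tricuspid inflow and RV volume on a uniform
#' time grid rebased to start at 0 — the boundary conditions a downstream
#' ventricular flow simulation consumes. Verifies that the cycle integral
#' of tricuspid inflow matches the RV outflow (pump plus pulmonary valve)
#' integral within 1%.
#'
#' @param traj An `lpm_trajectory` at periodic steady state.
#' @return Object of class `lpm_waveforms`: data frame with columns
#'   `time_s`, `tricuspid_inflow_ml_s`, `rv_volume_ml`, plus attributes
#'   `T_cycle` and `heart_rate`.
#' @export
lpm_export_waveforms <- function(traj) {
  rows <- .last_cycle_rows(traj)
  w <- data.frame(
    time_s = traj$time[rows] - traj$time[rows[1]],
    tricuspid_inflow_ml_s = traj$aux[rows, "Q_tc"],
    rv_volume_ml = traj$state[rows, "V_rv"]
  )
  dt <- traj$save_dt
  inflow_int <- sum(w$tricuspid_inflow_ml_s) * dt
  outflow_int <- sum(traj$state[rows, "Q_rvad"] + traj$aux[rows, "Q_pu"]) * dt
  if (abs(inflow_int - outflow_int) > 0.01 * max(inflow_int, 1)) {
    warning(sprintf(
      "tricuspid inflow integral (%.1f ml) and RV outflow integral (%.1f ml) differ by more than 1%%",
      inflow_int, outflow_int))
  }
  structure(w, T_cycle = traj$T_cycle, heart_rate = traj$params$heart_rate,
            class = c("lpm_waveforms", "data.frame"))
}

#' Write waveforms to CSV
#'
#' @param w An `lpm_waveforms` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
lpm_write_waveforms <- function(w, path) {
  utils::write.csv(as.data.frame(w)[, c("time_s", "tricuspid_inflow_ml_s",
                                        "rv_volume_ml")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read waveforms from CSV
#'
#' @param path CSV written by [lpm_write_waveforms()].
#' @return An `lpm_waveforms` object (cycle length taken from the grid).
#' @export
lpm_read_waveforms <- function(path) {
  w <- utils::read.csv(path)
  stopifnot(all(c("time_s", "tricuspid_inflow_ml_s", "rv_volume_ml")
                %in% names(w)))
  dt <- stats::median(diff(w$time_s))
  structure(w, T_cycle = w$time_s[nrow(w)] + dt,
            class = c("lpm_waveforms", "data.frame"))
}

# JSON keys follow the published hemodynamic-summary row labels
.summary_json_keys <- c(
  heart_rate = "Heart rate (bpm)",
  cardiac_output = "Cardiac output (L/min)",
  MAP = "Mean arterial pressure (mmHg)",
  mPAP = "Mean pulmonary arterial pressure (mmHg)",
  LAP = "Left atrial pressure (mmHg)",
  RAP = "Right atrial pressure (mmHg)",
  SVR = "Systemic vascular resistance (mmHg.s.mL-1)",
  PVR = "Pulmonary vascular resistance (mmHg.s.mL-1)")

#' Write a hemodynamic summary as JSON
#'
#' Keys of the core indices follow the standard clinical row labels
#' (e.g. `"Cardiac output (L/min)"`); the remaining fields are appended
#' under their internal names.
#'
#' @param s A `hemodynamic_summary`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
lpm_write_summary <- function(s, path) {
  core <- stats::setNames(
    lapply(names(.summary_json_keys), function(k) s[[k]]),
    unname(.summary_json_keys))
  extra <- s[setdiff(names(s), names(.summary_json_keys))]
  jsonlite::write_json(c(core, extra), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
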