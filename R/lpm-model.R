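.activation_cache <- new.env(parent = emptyenv())

#' Normalized chamber activation
#'
#' Double-Hill activation driving the time-varying elastance: with
#' \eqn{\sigma} the time since activation onset scaled by the activation
#' duration,
#' \deqn{e(\sigma) \propto \frac{(\sigma/a_1)^{m_1}}{1+(\sigma/a_1)^{m_1}}
#'       \cdot \frac{1}{1+(\sigma/a_2)^{m_2}},}
#' normalized so its maximum over the cycle is exactly 1. The function is
#' smooth, periodic with the cycle, 0 at onset and (to within ~1e-4) 0
#' throughout diastole.
#'
#' @param t Time, s (vectorized). Interpreted modulo the cycle.
#' @param timing List with `onset` and `duration`, fractions of the cycle.
#' @param T_cycle Cycle length, s.
#' @param shape Hill shape constants `a1`, `m1`, `a2`, `m2` on the
#'   duration-normalized time axis.
#' @return Activation in `[0, 1]`, same length as `t`.
#' @export
lpm_activation <- function(t, timing, T_cycle,
                           shape = list(a1 = 0.30, m1 = 1.9,
                                        a2 = 0.65, m2 = 21.9)) {
  if (!is.null(timing$shape)) shape <- utils::modifyList(shape, timing$shape)
  if (is.null(timing$onset) || is.null(timing$duration) ||
      timing$onset < 0 || timing$onset > 1 ||
      timing$duration <= 0 || timing$duration > 1) {
    stop("invalid activation timing: need onset in [0,1], duration in (0,1]")
  }
  raw <- function(sigma) {
    g1 <- (sigma / shape$a1)^shape$m1
    g2 <- (sigma / shape$a2)^shape$m2
    (g1 / (1 + g1)) / (1 + g2)
  }
  # peak of the raw double-Hill on a fine grid; depends only on the shape
  # constants, so memoize (this sits inside the ODE right-hand side)
  key <- paste0(shape$a1, "_", shape$m1, "_", shape$a2, "_", shape$m2)
  emax <- .activation_cache[[key]]
  if (is.null(emax)) {
    grid0 <- seq(0, 1.5, length.out = 2001)
    s0 <- grid0[which.max(raw(grid0))]
    emax <- stats::optimize(raw, c(max(0, s0 - 0.01), s0 + 0.01),
                            maximum = TRUE, tol = 1e-12)$objective
    assign(key, emax, envir = .activation_cache)
  }
  phase <- (t / T_cycle - timing$onset) %% 1
  sigma <- phase / timing$duration
  raw(sigma) / emax
}

#' Instantaneous chamber pressure
#'
#' Activation-weighted blend of the end-systolic and end-diastolic
#' pressure--volume laws (see [chamber_params()]). At activation 0 the
#' pressure equals the EDPVR value, at activation 1 the ESPVR value.
#'
#' @param V Chamber volume, ml (vectorized).
#' @param t Time, s (vectorized, recycled against `V`).
#' @param p A `chamber_params` object.
#' @param T_cycle Cycle length, s.
#' @return Pressure, mmHg.
#' @export
lpm_chamber_pressure <- function(V, t, p, T_cycle) {
  stopifnot(all(V >= 0))
  e <- lpm_activation(t, p$activation, T_cycle)
  P_ed <- p$edpvr_A * (exp(p$edpvr_B * (V - p$V0_ed)) - 1)
  dV <- V - p$V0_es
  P_es <- if (p$espvr_shape == "linear") {
    p$Ees * dV
  } else {
    # mild saturation above V0_es; slope Ees at V0_es
    p$Ees * dV / (1 + p$espvr_kappa * pmax(dV, 0))
  }
  e * P_es + (1 - e) * P_ed
}

#' Transvalvular flow
#'
#' Diode-plus-resistance valve law: forward flow proportional to the
#' pressure difference when the valve is open, exactly zero otherwise
#' (the tie at zero difference is closed). With an explicit open fraction
#' the flow scales linearly with it, supporting the optional first-order
#' opening dynamics.
#'
#' @param dp Pressure difference across the valve, mmHg (vectorized).
#' @param v A `valve_params` object.
#' @param state Open fraction in `[0, 1]`; `NULL` (default) means the
#'   instantaneous diode: fully open iff `dp > 0`.
#' @return Flow, ml/s; never negative.
#' @export
lpm_valve_flow <- function(dp, v, state = NULL) {
  if (is.null(state)) {
    ifelse(dp > 0, dp / v$open_resistance, 0)
  } else {
    stopifnot(all(state >= 0 & state <= 1))
    state * pmax(dp, 0) / v$open_resistance
  }
}

#' Pump pressure head
#'
#' Evaluates the quadratic head--flow--speed law of [pump_params()]. RPM is
#' converted to rad/s internally. Flows outside the fitted operating range
#' trigger a warning attribute consumer code may surface.
#'
#' @param Q Pump flow, ml/s (vectorized).
#' @param p A `pump_params` object.
#' @param warn Warn on extrapolation outside `p$Q_range`.
#' @return Pressure head (outlet minus inlet at equilibrium), mmHg.
#' @export
lpm_pump_head <- function(Q, p, warn = FALSE) {
  omega <- p$speed * 2 * pi / 60
  if (warn && any(Q < p$Q_range[1] | Q > p$Q_range[2])) {
    warning("pump flow outside fitted HQ range; head extrapolated")
  }
  p$coeff_q2 * Q^2 + p$coeff_q1 * Q + p$coeff_w2 * omega^2
}

# State vector layout of the closed loop
.lpm_state_names <- c("V_la", "V_lv", "V_ra", "V_rv",
                      "V_sa", "V_sv", "V_pa", "V_pv",
                      "Q_sys", "Q_pul", "Q_lvad", "Q_rvad")

.lpm_initial_state <- function(p) {
  v <- p$vessels
  c(V_la = p$init$V_la, V_lv = p$init$V_lv,
    V_ra = p$init$V_ra, V_rv = p$init$V_rv,
    V_sa = v$sa$V_un + v$sa$C * p$init$P_sa,
    V_sv = v$sv$V_un + v$sv$C * p$init$P_sv,
    V_pa = v$pa$V_un + v$pa$C * p$init$P_pa,
    V_pv = v$pv$V_un + v$pv$C * p$init$P_pv,
    Q_sys = p$init$Q_sys, Q_pul = p$init$Q_pul,
    Q_lvad = p$init$Q_lvad, Q_rvad = p$init$Q_rvad)
}

#' Time derivative of the closed-loop state
#'
#' Right-hand side of the circulation ODE. Eight volume states (four
#' chambers, four vascular compartments), two vascular inertial flows
#' (aorta and pulmonary artery) and two pump branch flows. The sum of all
#' volume derivatives is identically zero: the loop conserves blood volume
#' to round-off.
#'
#' @param t Time, s.
#' @param y Named state vector (see `rvadflow:::.lpm_state_names`).
#' @param p An `lpm_params` object.
#' @param aux Also return the instantaneous pressures and flows.
#' @return Derivative vector; with `aux = TRUE` a list `list(dy, aux)`.
#' @export
lpm_rhs <- function(t, y, p, aux = FALSE) {
  if (any(!is.finite(y))) {
    stop("non-finite state at t = ", signif(t, 6),
         "; integration diverged (check dt and parameters)")
  }
  T_cycle <- 60 / p$heart_rate
  ch <- p$chambers; vs <- p$vessels; va <- p$valves; pu <- p$pumps

  # positional access (layout .lpm_state_names) keeps the hot loop cheap
  P_la <- lpm_chamber_pressure(y[1], t, ch$la, T_cycle)
  P_lv <- lpm_chamber_pressure(y[2], t, ch$lv, T_cycle)
  P_ra <- lpm_chamber_pressure(y[3], t, ch$ra, T_cycle)
  P_rv <- lpm_chamber_pressure(y[4], t, ch$rv, T_cycle)
  P_sa <- (y[5] - vs$sa$V_un) / vs$sa$C
  P_sv <- (y[6] - vs$sv$V_un) / vs$sv$C
  P_pa <- (y[7] - vs$pa$V_un) / vs$pa$C
  P_pv <- (y[8] - vs$pv$V_un) / vs$pv$C

  Q_mi <- lpm_valve_flow(P_la - P_lv, va$mitral)
  Q_ao <- lpm_valve_flow(P_lv - P_sa, va$aortic)
  Q_tc <- lpm_valve_flow(P_ra - P_rv, va$tricuspid)
  Q_pu <- lpm_valve_flow(P_rv - P_pa, va$pulmonary)
  Q_sys  <- y[9]
  Q_pul  <- y[10]
  Q_lvad <- y[11]
  Q_rvad <- y[12]
  Q_svra <- (P_sv - P_ra) / vs$sv$R   # veins: no valve, bidirectional
  Q_pvla <- (P_pv - P_la) / vs$pv$R

  dy <- c(
    V_la = Q_pvla - Q_mi,
    V_lv = Q_mi - Q_ao - Q_lvad,
    V_ra = Q_svra - Q_tc,
    V_rv = Q_tc - Q_pu - Q_rvad,
    V_sa = Q_ao + Q_lvad - Q_sys,
    V_sv = Q_sys - Q_svra,
    V_pa = Q_pu + Q_rvad - Q_pul,
    V_pv = Q_pul - Q_pvla,
    Q_sys = (P_sa - P_sv - vs$sa$R * Q_sys) / vs$sa$L,
    Q_pul = (P_pa - P_pv - vs$pa$R * Q_pul) / vs$pa$L,
    # a stopped pump is taken as a clamped (closed) branch
    Q_lvad = if (pu$lvad$speed > 0) {
      (P_lv + lpm_pump_head(Q_lvad, pu$lvad) - P_sa) / pu$lvad$inertance
    } else -Q_lvad / 0.01,
    Q_rvad = if (pu$rvad$speed > 0) {
      (P_rv + lpm_pump_head(Q_rvad, pu$rvad) - P_pa) / pu$rvad$inertance
    } else -Q_rvad / 0.01
  )
  if (!aux) return(dy)
  list(dy = dy,
       aux = c(P_la = P_la, P_lv = P_lv, P_ra = P_ra, P_rv = P_rv,
               P_sa = P_sa, P_sv = P_sv, P_pa = P_pa, P_pv = P_pv,
               Q_mi = Q_mi, Q_ao = Q_ao, Q_tc = Q_tc, Q_pu = Q_pu,
               Q_svra = Q_svra, Q_pvla = Q_pvla))
}
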