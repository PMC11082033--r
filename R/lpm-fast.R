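# Inlined fixed-step RK4 loop for the closed loop.
#
# The readable right-hand side lives in lpm_rhs(); this file carries a
# flattened version of the same equations with all parameter-list lookups
# hoisted out of the loop and the periodic activation functions tabulated
# on the half-step grid (RK4 only ever evaluates at t, t + dt/2 and
# t + dt). A regression test asserts step-for-step agreement between the
# two paths, so the fast loop is an optimisation, not a second model.

.lpm_run_fast <- function(p, n_cycles, dt, save_every) {
  T_cycle <- 60 / p$heart_rate
  steps_per_cycle <- round(T_cycle / dt)
  if (abs(steps_per_cycle * dt - T_cycle) > 1e-9 * T_cycle) {
    # non-commensurate step: activation table indexing needs dt | T
    stop("dt must divide the cycle length 60/heart_rate")
  }
  n_steps <- n_cycles * steps_per_cycle
  n_half <- 2L * steps_per_cycle

  ch <- p$chambers; vs <- p$vessels; va <- p$valves; pu <- p$pumps
  th <- seq(0, T_cycle, length.out = n_half + 1L)[seq_len(n_half)]
  act <- lapply(ch, function(cp) lpm_activation(th, cp$activation, T_cycle))

  # chamber scalars
  A_la <- ch$la$edpvr_A; B_la <- ch$la$edpvr_B; V0d_la <- ch$la$V0_ed
  E_la <- ch$la$Ees; V0s_la <- ch$la$V0_es
  A_lv <- ch$lv$edpvr_A; B_lv <- ch$lv$edpvr_B; V0d_lv <- ch$lv$V0_ed
  E_lv <- ch$lv$Ees; V0s_lv <- ch$lv$V0_es; k_lv <- ch$lv$espvr_kappa
  A_ra <- ch$ra$edpvr_A; B_ra <- ch$ra$edpvr_B; V0d_ra <- ch$ra$V0_ed
  E_ra <- ch$ra$Ees; V0s_ra <- ch$ra$V0_es
  A_rv <- ch$rv$edpvr_A; B_rv <- ch$rv$edpvr_B; V0d_rv <- ch$rv$V0_ed
  E_rv <- ch$rv$Ees; V0s_rv <- ch$rv$V0_es; k_rv <- ch$rv$espvr_kappa
  a_la <- act$la; a_lv <- act$lv; a_ra <- act$ra; a_rv <- act$rv

  # vessels, valves, pumps
  Vun_sa <- vs$sa$V_un; C_sa <- vs$sa$C; R_sa <- vs$sa$R; L_sa <- vs$sa$L
  Vun_sv <- vs$sv$V_un; C_sv <- vs$sv$C; R_sv <- vs$sv$R
  Vun_pa <- vs$pa$V_un; C_pa <- vs$pa$C; R_pa <- vs$pa$R; L_pa <- vs$pa$L
  Vun_pv <- vs$pv$V_un; C_pv <- vs$pv$C; R_pv <- vs$pv$R
  R_mi <- va$mitral$open_resistance; R_ao <- va$aortic$open_resistance
  R_tc <- va$tricuspid$open_resistance; R_pu <- va$pulmonary$open_resistance
  wL <- pu$lvad$speed * 2 * pi / 60; wR <- pu$rvad$speed * 2 * pi / 60
  q2L <- pu$lvad$coeff_q2; q1L <- pu$lvad$coeff_q1
  hL0 <- pu$lvad$coeff_w2 * wL^2; LL <- pu$lvad$inertance
  q2R <- pu$rvad$coeff_q2; q1R <- pu$rvad$coeff_q1
  hR0 <- pu$rvad$coeff_w2 * wR^2; LR <- pu$rvad$inertance
  onL <- pu$lvad$speed > 0; onR <- pu$rvad$speed > 0

  deriv <- function(ih, y) {
    # ih: half-step index of the time point (activation table column)
    ia <- ih %% n_half + 1L
    e_la <- a_la[ia]; e_lv <- a_lv[ia]; e_ra <- a_ra[ia]; e_rv <- a_rv[ia]

    P_la <- e_la * E_la * (y[1] - V0s_la) +
      (1 - e_la) * A_la * (exp(B_la * (y[1] - V0d_la)) - 1)
    dVlv <- y[2] - V0s_lv
    P_lv <- e_lv * E_lv * dVlv / (1 + k_lv * max(dVlv, 0)) +
      (1 - e_lv) * A_lv * (exp(B_lv * (y[2] - V0d_lv)) - 1)
    P_ra <- e_ra * E_ra * (y[3] - V0s_ra) +
      (1 - e_ra) * A_ra * (exp(B_ra * (y[3] - V0d_ra)) - 1)
    dVrv <- y[4] - V0s_rv
    P_rv <- e_rv * E_rv * dVrv / (1 + k_rv * max(dVrv, 0)) +
      (1 - e_rv) * A_rv * (exp(B_rv * (y[4] - V0d_rv)) - 1)
    P_sa <- (y[5] - Vun_sa) / C_sa
    P_sv <- (y[6] - Vun_sv) / C_sv
    P_pa <- (y[7] - Vun_pa) / C_pa
    P_pv <- (y[8] - Vun_pv) / C_pv

    Q_mi <- if (P_la > P_lv) (P_la - P_lv) / R_mi else 0
    Q_ao <- if (P_lv > P_sa) (P_lv - P_sa) / R_ao else 0
    Q_tc <- if (P_ra > P_rv) (P_ra - P_rv) / R_tc else 0
    Q_pu <- if (P_rv > P_pa) (P_rv - P_pa) / R_pu else 0
    Q_sys <- y[9]; Q_pul <- y[10]; Q_lv_p <- y[11]; Q_rv_p <- y[12]
    Q_svra <- (P_sv - P_ra) / R_sv
    Q_pvla <- (P_pv - P_la) / R_pv

    c(Q_pvla - Q_mi,
      Q_mi - Q_ao - Q_lv_p,
      Q_svra - Q_tc,
      Q_tc - Q_pu - Q_rv_p,
      Q_ao + Q_lv_p - Q_sys,
      Q_sys - Q_svra,
      Q_pu + Q_rv_p - Q_pul,
      Q_pul - Q_pvla,
      (P_sa - P_sv - R_sa * Q_sys) / L_sa,
      (P_pa - P_pv - R_pa * Q_pul) / L_pa,
      if (onL) (P_lv + hL0 + q1L * Q_lv_p + q2L * Q_lv_p * Q_lv_p - P_sa) / LL
      else -Q_lv_p / 0.01,
      if (onR) (P_rv + hR0 + q1R * Q_rv_p + q2R * Q_rv_p * Q_rv_p - P_pa) / LR
      else -Q_rv_p / 0.01)
  }

  y <- unname(.lpm_initial_state(p))
  n_save <- floor(n_steps / save_every) + 1L
  out <- matrix(NA_real_, n_save, 12L,
                dimnames = list(NULL, .lpm_state_names))
  times <- numeric(n_save)
  out[1L, ] <- y
  row <- 1L
  sixth <- dt / 6
  half <- dt / 2
  for (i in seq_len(n_steps)) {
    ih <- 2L * (i - 1L)
    k1 <- deriv(ih, y)
    k2 <- deriv(ih + 1L, y + half * k1)
    k3 <- deriv(ih + 1L, y + half * k2)
    k4 <- deriv(ih + 2L, y + dt * k3)
    y <- y + sixth * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.finite(y[1])) {
      stop("non-finite state at step ", i, "; integration diverged")
    }
    if (i %% save_every == 0L) {
      row <- row + 1L
      out[row, ] <- y
      times[row] <- i * dt
    }
  }
  list(time = times[seq_len(row)], state = out[seq_len(row), , drop = FALSE])
}

# vectorized reconstruction of pressures/flows at the saved times
.lpm_aux <- function(time, state, p) {
  T_cycle <- 60 / p$heart_rate
  ch <- p$chambers; vs <- p$vessels; va <- p$valves
  P_la <- lpm_chamber_pressure(state[, 1], time, ch$la, T_cycle)
  P_lv <- lpm_chamber_pressure(state[, 2], time, ch$lv, T_cycle)
  P_ra <- lpm_chamber_pressure(state[, 3], time, ch$ra, T_cycle)
  P_rv <- lpm_chamber_pressure(state[, 4], time, ch$rv, T_cycle)
  P_sa <- (state[, 5] - vs$sa$V_un) / vs$sa$C
  P_sv <- (state[, 6] - vs$sv$V_un) / vs$sv$C
  P_pa <- (state[, 7] - vs$pa$V_un) / vs$pa$C
  P_pv <- (state[, 8] - vs$pv$V_un) / vs$pv$C
  cbind(P_la = P_la, P_lv = P_lv, P_ra = P_ra, P_rv = P_rv,
        P_sa = P_sa, P_sv = P_sv, P_pa = P_pa, P_pv = P_pv,
        Q_mi = lpm_valve_flow(P_la - P_lv, va$mitral),
        Q_ao = lpm_valve_flow(P_lv - P_sa, va$aortic),
        Q_tc = lpm_valve_flow(P_ra - P_rv, va$tricuspid),
        Q_pu = lpm_valve_flow(P_rv - P_pa, va$pulmonary),
        Q_svra = (P_sv - P_ra) / vs$sv$R,
        Q_pvla = (P_pv - P_la) / vs$pv$R)
}
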