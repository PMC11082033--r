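#' Heart-chamber parameters
#'
#' Builds the parameter block for one elastance chamber. Chamber pressure is
#' the activation-weighted blend of an end-systolic pressure--volume relation
#' (ESPVR) and a nonlinear end-diastolic relation (EDPVR),
#' \deqn{P(V,t) = e(t)\,P_{es}(V) + (1-e(t))\,P_{ed}(V),}
#' with \eqn{P_{ed} = A(\exp(B(V-V_{0,ed}))-1)} and, for a linear ESPVR,
#' \eqn{P_{es} = E_{es}(V-V_{0,es})}. Ventricles use a mildly saturating
#' (curvilinear) ESPVR, atria a linear one.
#'
#' @param Ees End-systolic elastance, mmHg/ml.
#' @param V0_es Unstressed end-systolic volume, ml.
#' @param V0_ed Unstressed end-diastolic volume, ml.
#' @param edpvr_A EDPVR scale, mmHg.
#' @param edpvr_B EDPVR exponent, 1/ml.
#' @param espvr_shape `"linear"` or `"curvilinear"`.
#' @param espvr_kappa Saturation coefficient of the curvilinear ESPVR, 1/ml;
#'   ignored for the linear shape.
#' @param activation Activation timing, a list with `onset` and `duration`
#'   as fractions of the cardiac cycle (see [lpm_activation()]).
#' @return A list of class `chamber_params`.
#' @export
chamber_params <- function(Ees, V0_es, V0_ed, edpvr_A, edpvr_B,
                           espvr_shape = c("curvilinear", "linear"),
                           espvr_kappa = 0.001,
                           activation = list(onset = 0, duration = 0.4)) {
  espvr_shape <- match.arg(espvr_shape)
  stopifnot(Ees > 0, edpvr_A > 0, edpvr_B > 0, espvr_kappa >= 0)
  if (!is.list(activation) ||
      is.null(activation$onset) || is.null(activation$duration) ||
      activation$onset < 0 || activation$onset > 1 ||
      activation$duration <= 0 || activation$duration > 1) {
    stop("activation timing must give onset in [0,1] and duration in (0,1]")
  }
  structure(list(Ees = Ees, V0_es = V0_es, V0_ed = V0_ed,
                 edpvr_A = edpvr_A, edpvr_B = edpvr_B,
                 espvr_shape = espvr_shape, espvr_kappa = espvr_kappa,
                 activation = activation),
            class = "chamber_params")
}

#' Vascular compartment parameters
#'
#' One lumped compartment: compliance chamber with an outflow resistance and,
#' for the aorta and pulmonary artery only, an outflow inertance.
#'
#' @param R Outflow resistance, mmHg·s/ml.
#' @param C Compliance, ml/mmHg.
#' @param L Outflow inertance, mmHg·s^2/ml; 0 for all compartments except the
#'   aorta and the pulmonary artery.
#' @param V_un Unstressed volume, ml.
#' @return A list of class `vascular_params`.
#' @export
vascular_params <- function(R, C, L = 0, V_un = 0) {
  stopifnot(R > 0, C > 0, L >= 0, V_un >= 0)
  structure(list(R = R, C = C, L = L, V_un = V_un),
            class = "vascular_params")
}

#' Hydraulic valve parameters
#'
#' Ideal diode plus a (small) open resistance: flow is driven by the pressure
#' difference across the valve and is exactly zero for any non-positive
#' difference. An optional first-order opening state is available through
#' [lpm_valve_flow()].
#'
#' @param open_resistance Resistance of the open valve, mmHg·s/ml.
#' @param tau Opening/closing time constant, s; 0 means instantaneous.
#' @return A list of class `valve_params`.
#' @export
valve_params <- function(open_resistance, tau = 0) {
  stopifnot(open_resistance > 0, tau >= 0)
  structure(list(open_resistance = open_resistance, tau = tau),
            class = "valve_params")
}

#' Rotary blood pump parameters
#'
#' Head--flow--speed law of a continuous-flow pump,
#' \deqn{\Delta P = c_{q2} Q^2 + c_{q1} Q + c_{w2}\,\omega^2,}
#' with \eqn{Q} in ml/s, \eqn{\omega} the rotational speed in rad/s
#' (converted internally from RPM) and \eqn{\Delta P} in mmHg. With
#' \eqn{c_{q2} < 0} and \eqn{c_{q1} \le 0} the head is non-increasing in flow
#' at fixed speed, as a centrifugal HQ curve requires.
#'
#' @param speed Rotational speed, RPM.
#' @param coeff_q2 Quadratic flow coefficient, mmHg·s^2/ml^2 (negative).
#' @param coeff_q1 Linear flow coefficient, mmHg·s/ml (non-positive).
#' @param coeff_w2 Speed-squared coefficient, mmHg·s^2/rad^2.
#' @param inertance Inlet-to-outlet fluid inertance of the pump branch,
#'   mmHg·s^2/ml.
#' @param Q_range Fitted operating range of the HQ data, ml/s.
#' @return A list of class `pump_params`.
#' @export
pump_params <- function(speed, coeff_q2, coeff_q1 = 0, coeff_w2,
                        inertance = 0.02, Q_range = c(-20, 180)) {
  stopifnot(speed >= 0, coeff_q2 < 0, coeff_q1 <= 0, coeff_w2 > 0,
            inertance > 0)
  structure(list(speed = speed, coeff_q2 = coeff_q2, coeff_q1 = coeff_q1,
                 coeff_w2 = coeff_w2, inertance = inertance,
                 Q_range = Q_range),
            class = "pump_params")
}

#' Full closed-loop model parameter set
#'
#' Assembles chambers, vascular compartments, valves and pumps into one
#' parameter object. Two presets ship with the package:
#'
#' * `"bivad_failure"`: severe biventricular failure (ventricular
#'   end-systolic elastances reduced to 0.86 and 0.5 mmHg/ml for the LV and
#'   RV, dilated unstressed volumes) supported by two rotary pumps at
#'   5400 RPM (left) and 4300 RPM (right). Values printed in the study body
#'   (elastances, pump speeds, heart rate) are hard defaults; the remaining
#'   compartment values are a documented fallback set calibrated so the
#'   periodic steady state reproduces the published hemodynamic summary.
#' * `"healthy"`: healthy baseline elastances (3.54 and 1.75 mmHg/ml),
#'   pumps off.
#'
#' @param preset `"bivad_failure"` or `"healthy"`.
#' @param ... Named replacements applied on top of the preset with
#'   [utils::modifyList()] semantics, e.g.
#'   `lpm_params(pumps = list(rvad = list(speed = 5000)))`.
#' @return A nested list of class `lpm_params` with elements `heart_rate`
#'   (bpm), `chambers` (`la`, `lv`, `ra`, `rv`), `vessels` (`sa`, `sv`,
#'   `pa`, `pv`), `valves` (`mitral`, `aortic`, `tricuspid`, `pulmonary`),
#'   `pumps` (`lvad`, `rvad`) and `init` (initial volumes/flows).
#' @export
lpm_params <- function(preset = c("bivad_failure", "healthy"), ...) {
  preset <- match.arg(preset)
  p <- if (preset == "bivad_failure") .preset_bivad() else .preset_healthy()
  dots <- list(...)
  if (length(dots)) p <- utils::modifyList(p, dots)
  p <- .restore_param_classes(p)
  validate_lpm_params(p)
  p
}

.vent_timing <- list(onset = 0, duration = 0.56, shape = list(a2 = 0.80))
.atr_timing  <- list(onset = 0.84, duration = 0.18)

.preset_bivad <- function() {
  structure(list(
    heart_rate = 75,
    chambers = list(
      la = chamber_params(Ees = 0.40, V0_es = 25, V0_ed = 20,
                          edpvr_A = 0.45, edpvr_B = 0.050,
                          espvr_shape = "linear", activation = .atr_timing),
      lv = chamber_params(Ees = 0.86, V0_es = 120, V0_ed = 100,
                          edpvr_A = 0.30, edpvr_B = 0.043,
                          espvr_shape = "curvilinear",
                          activation = .vent_timing),
      ra = chamber_params(Ees = 0.50, V0_es = 20, V0_ed = 15,
                          edpvr_A = 0.35, edpvr_B = 0.045,
                          espvr_shape = "linear", activation = .atr_timing),
      rv = chamber_params(Ees = 0.50, V0_es = 220, V0_ed = 160,
                          edpvr_A = 0.08, edpvr_B = 0.038,
                          espvr_kappa = 0.005,
                          espvr_shape = "curvilinear",
                          activation = .vent_timing)),
    vessels = list(
      sa = vascular_params(R = 0.900, C = 1.3, L = 5e-4, V_un = 600),
      sv = vascular_params(R = 0.034, C = 70,  L = 0,    V_un = 2800),
      pa = vascular_params(R = 0.090, C = 4.5, L = 3e-4, V_un = 120),
      pv = vascular_params(R = 0.0173, C = 12, L = 0,    V_un = 400)),
    valves = list(
      mitral    = valve_params(0.005),
      aortic    = valve_params(0.008),
      tricuspid = valve_params(0.004),
      pulmonary = valve_params(0.006)),
    pumps = list(
      lvad = pump_params(speed = 5400, coeff_q2 = -0.010928,
                         coeff_w2 = 4.589e-4),
      rvad = pump_params(speed = 4300, coeff_q2 = -0.010928,
                         coeff_w2 = 4.589e-4)),
    init = list(
      V_la = 90, V_lv = 180, V_ra = 84, V_rv = 250,
      P_sa = 87, P_sv = 10.8, P_pa = 24, P_pv = 15.5,
      Q_sys = 80, Q_pul = 80, Q_lvad = 80, Q_rvad = 80)
  ), class = "lpm_params")
}

.preset_healthy <- function() {
  p <- .preset_bivad()
  p$chambers$lv <- chamber_params(Ees = 3.54, V0_es = 20, V0_ed = 10,
                                  edpvr_A = 0.30, edpvr_B = 0.033,
                                  espvr_shape = "curvilinear",
                                  activation = .vent_timing)
  p$chambers$rv <- chamber_params(Ees = 1.75, V0_es = 25, V0_ed = 15,
                                  edpvr_A = 0.30, edpvr_B = 0.030,
                                  espvr_shape = "curvilinear",
                                  activation = .vent_timing)
  p$pumps$lvad$speed <- 0
  p$pumps$rvad$speed <- 0
  p$init <- list(V_la = 60, V_lv = 130, V_ra = 60, V_rv = 130,
                 P_sa = 90, P_sv = 8, P_pa = 18, P_pv = 10,
                 Q_sys = 80, Q_pul = 80, Q_lvad = 0, Q_rvad = 0)
  p
}

# modifyList drops S3 classes of replaced sub-lists; put them back
.restore_param_classes <- function(p) {
  for (nm in names(p$chambers)) class(p$chambers[[nm]]) <- "chamber_params"
  for (nm in names(p$vessels))  class(p$vessels[[nm]])  <- "vascular_params"
  for (nm in names(p$valves))   class(p$valves[[nm]])   <- "valve_params"
  for (nm in names(p$pumps))    class(p$pumps[[nm]])    <- "pump_params"
  class(p) <- "lpm_params"
  p
}

#' Validate a full parameter set
#'
#' Checks positivity and structural invariants: elastances and resistances
#' positive, inertance only on the aorta and pulmonary artery, atria linear /
#' ventricles curvilinear ESPVR, activation fractions in range.
#'
#' @param p An `lpm_params` object.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_lpm_params <- function(p) {
  stopifnot(inherits(p, "lpm_params"), p$heart_rate > 0)
  need <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  need(all(c("la", "lv", "ra", "rv") %in% names(p$chambers)),
       "chambers la, lv, ra, rv required")
  need(all(c("sa", "sv", "pa", "pv") %in% names(p$vessels)),
       "vessels sa, sv, pa, pv required")
  for (nm in names(p$chambers)) {
    ch <- p$chambers[[nm]]
    need(ch$Ees > 0 && ch$edpvr_B > 0, paste0(nm, ": Ees and edpvr_B > 0"))
    a <- ch$activation
    need(a$onset >= 0 && a$onset <= 1 && a$duration > 0 && a$duration <= 1,
         paste0(nm, ": activation fractions out of range"))
  }
  need(p$chambers$la$espvr_shape == "linear" &&
       p$chambers$ra$espvr_shape == "linear",
       "atria must use a linear ESPVR")
  need(p$chambers$lv$espvr_shape == "curvilinear" &&
       p$chambers$rv$espvr_shape == "curvilinear",
       "ventricles must use a curvilinear ESPVR")
  for (nm in names(p$vessels)) {
    v <- p$vessels[[nm]]
    need(v$R > 0 && v$C > 0 && v$L >= 0, paste0(nm, ": R,C > 0 and L >= 0"))
  }
  need(p$vessels$sv$L == 0 && p$vessels$pv$L == 0,
       "inertance only on the aorta and pulmonary artery")
  for (nm in names(p$pumps)) {
    pm <- p$pumps[[nm]]
    need(pm$coeff_q2 < 0 && pm$coeff_q1 <= 0 && pm$coeff_w2 > 0,
         paste0(nm, ": pump head must be non-increasing in flow"))
  }
  invisible(p)
}

#' Read a model configuration file
#'
#' Loads a YAML parameter file and merges it onto a preset. The file mirrors
#' the structure of [lpm_params()]; any subset of keys may be given. The
#' shipped `inst/extdata/bivad_failure.yaml` documents every field with its
#' units.
#'
#' @param path Path to a YAML file.
#' @param preset Base preset the file overrides.
#' @return An `lpm_params` object.
#' @export
lpm_read_config <- function(path, preset = "bivad_failure") {
  cfg <- yaml::read_yaml(path)
  hr <- cfg$heart_rate
  cfg$heart_rate <- NULL
  p <- do.call(lpm_params, c(list(preset = preset), cfg))
  if (!is.null(hr)) p$heart_rate <- hr
  validate_lpm_params(p)
}
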