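# Closed-loop model configuration: severe biventricular failure supported
# by two rotary pumps. This file mirrors the structure of lpm_params();
# any key may be omitted, in which case the preset default applies.
#
# Units: pressures mmHg, volumes ml, flows ml/s, resistances mmHg.s/ml,
# compliances ml/mmHg, inertances mmHg.s^2/ml, elastances mmHg/ml,
# pump speed RPM, times s. Activation onset/duration are cycle fractions.
#
# Elastances (LV 0.86, RV 0.5), pump speeds (5400/4300 RPM) and heart rate
# (75 bpm) are the published study values. The remaining compartment values
# are the package's documented fallback set, calibrated so the periodic
# steady state reproduces the published cycle-averaged hemodynamics.

heart_rate: 75            # bpm

chambers:
  la:
    Ees: 0.40             # mmHg/ml, linear ESPVR
    V0_es: 25
    V0_ed: 20
    edpvr_A: 0.45         # mmHg
    edpvr_B: 0.050        # 1/ml
    activation: {onset: 0.84, duration: 0.18}
  lv:
    Ees: 0.86             # reduced from healthy 3.54 mmHg/ml
    V0_es: 120
    V0_ed: 100
    edpvr_A: 0.30
    edpvr_B: 0.043
    espvr_kappa: 0.001    # 1/ml, curvilinear ESPVR saturation
    activation: {onset: 0.0, duration: 0.56, shape: {a2: 0.80}}
  ra:
    Ees: 0.50
    V0_es: 20
    V0_ed: 15
    edpvr_A: 0.35
    edpvr_B: 0.045
    activation: {onset: 0.84, duration: 0.18}
  rv:
    Ees: 0.50             # reduced from healthy 1.75 mmHg/ml
    V0_es: 220            # dilated
    V0_ed: 160            # dilated
    edpvr_A: 0.08
    edpvr_B: 0.038
    espvr_kappa: 0.005
    activation: {onset: 0.0, duration: 0.56, shape: {a2: 0.80}}

vessels:                   # R = outflow resistance of the compartment
  sa: {R: 0.900,  C: 1.3, L: 5.0e-4, V_un: 600}   # systemic arteries (aorta)
  sv: {R: 0.034,  C: 70,  L: 0.0,    V_un: 2800}  # systemic veins
  pa: {R: 0.090,  C: 4.5, L: 3.0e-4, V_un: 120}   # pulmonary artery
  pv: {R: 0.0173, C: 12,  L: 0.0,    V_un: 400}   # pulmonary veins

valves:                    # diode + open resistance
  mitral:    {open_resistance: 0.005}
  aortic:    {open_resistance: 0.008}
  tricuspid: {open_resistance: 0.004}
  pulmonary: {open_resistance: 0.006}

pumps:                     # head = coeff_q2*Q^2 + coeff_q1*Q + coeff_w2*omega^2
  lvad:                    # omega in rad/s (converted from RPM internally)
    speed: 5400            # RPM
    coeff_q2: -0.010928    # mmHg.s^2/ml^2
    coeff_q1: 0.0          # mmHg.s/ml
    coeff_w2: 4.589e-4     # mmHg.s^2/rad^2
    inertance: 0.02        # mmHg.s^2/ml
  rvad:
    speed: 4300
    coeff_q2: -0.010928
    coeff_q1: 0.0
    coeff_w2: 4.589e-4
    inertance: 0.02

init:                      # initial volumes (ml), pressures (mmHg), flows (ml/s)
  V_la: 90
  V_lv: 180
  V_ra: 84
  V_rv: 250
  P_sa: 87
  P_sv: 10.8
  P_pa: 24
  P_pv: 15.5
  Q_sys: 80
  Q_pul: 80
  Q_lvad: 80
  Q_rvad: 80
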