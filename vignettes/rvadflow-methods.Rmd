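---
title: "Methods: closed-loop BiVAD hemodynamics and thrombosis-risk flow metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop BiVAD hemodynamics and thrombosis-risk flow metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rvadflow` couples two desk-scale models: a closed-loop lumped-parameter
(0-D) circulation of severe biventricular failure supported by two rotary
blood pumps, and a set of discrete flow-metric kernels that quantify
thrombosis risk on time series of velocity fields over a masked
structured grid. A synthetic ventricle-flow generator with a
cannulation-depth surrogate connects the two, so the whole chain — from
chamber elastances to washout curves — runs in seconds and is testable
against closed-form oracles. This vignette records the model equations,
the tunable parameters, the numerical choices, and what the synthetic
cases can and cannot say about patient-specific flow.

## The closed loop

The circulation has four elastance chambers (LA, LV, RA, RV), four
vascular compartments (systemic arteries and veins, pulmonary artery and
veins), four diode valves, and two rotary pumps (left: LV to aorta at
5400 RPM; right: RV to pulmonary artery at 4300 RPM). State variables
are the eight blood volumes, two vascular inertial flows (aorta and
pulmonary artery only — the segments where blood acceleration matters),
and the two pump branch flows; the sum of the volume derivatives is
identically zero, so total blood volume is conserved to round-off.

**Chambers.** Pressure blends an end-systolic and an end-diastolic law
with a normalized activation $e(t)$:

$$P(V,t) = e(t)\,P_{es}(V) + (1-e(t))\,P_{ed}(V), \qquad
  P_{ed}(V) = A\left(e^{B(V-V_{0,ed})}-1\right).$$

Atria use a linear ESPVR $P_{es}=E_{es}(V-V_{0,es})$; ventricles use a
mildly saturating (curvilinear) form
$P_{es}=E_{es}\Delta V/(1+\kappa\,\Delta V_+)$ whose slope at the
unstressed volume is exactly $E_{es}$. The curvature $\kappa$ (default
0.001/ml LV, 0.005/ml RV) caps the systolic pressure of the dilated
failing RV — which is also what keeps the pulmonary valve shut under
full right-sided support, as the simulated condition requires.

**Activation.** A normalized double-Hill waveform
$e \propto \frac{(\sigma/a_1)^{m_1}}{1+(\sigma/a_1)^{m_1}}
\cdot\frac{1}{1+(\sigma/a_2)^{m_2}}$, with $\sigma$ the onset-shifted
time scaled by the activation duration, and the peak normalized to 1 by
a cached `optimize()` pass. Defaults: $a_1=0.30$, $m_1=1.9$, $m_2=21.9$;
ventricles use duration 0.56 of the cycle with plateau $a_2=0.80$, atria
onset 0.84 and duration 0.18. The long ventricular plateau is a
deliberate choice: with a continuous-flow pump draining the RV, the
stroke volume is essentially the pump outflow integrated over the
tricuspid-closed fraction of the cycle, and a severe-failure systole is
prolonged. The atrial timing places the A wave just before systole, so
the exported tricuspid inflow shows the expected two peaks (E and A).

**Valves and pumps.** Valves are ideal diodes with a small open
resistance; flow is exactly zero for any non-positive pressure
difference (the tie at zero is closed), and an optional first-order
opening state is available. Each pump follows a head–flow–speed law
$\Delta P = c_{q2}Q^2 + c_{q1}Q + c_{w2}\omega^2$ ($\omega$ in rad/s,
converted from RPM at the point of evaluation only), with
$c_{q2}<0,\ c_{q1}\le 0$ so the head is non-increasing in flow; the pump
branch carries a small inertance so its flow is a smooth state rather
than an algebraic root.

**Parameter provenance.** The values printed in the study body are hard
defaults: heart rate 75 bpm, ventricular end-systolic elastances reduced
to 0.86 (LV) and 0.5 (RV) mmHg/ml from healthy 3.54/1.75, pump speeds
5400/4300 RPM. Everything else (compartment R/C/L, unstressed volumes,
EDPVR constants, pump coefficients) ships as a documented fallback set,
calibrated once so the periodic steady state reproduces the published
cycle-averaged summary: CO 5.14 L/min, MAP 87.5, mPAP 24.0, LAP 14.7,
RAP 7.4 mmHg, SVR 0.934, PVR 0.108 mmHg·s/ml, RV stroke volume 36.5 ml,
EF 12.3% — each within 5% of the published row, with the pulmonary
valve closed throughout the cycle. Both pumps share one coefficient set
(two units of the same device). The full set, with units, lives in
`inst/extdata/bivad_failure.yaml`.

**Integration.** Fixed-step classical RK4 at the reference step
0.0002 s (an adaptive `lsoda` option exists for cross-checks); the
diode laws make the right-hand side non-smooth, which a fixed small step
handles more predictably than error-controlled stepping. The hot loop is
an inlined, flattened copy of the readable right-hand side with the
periodic activation tabulated on the half-step grid; a regression test
pins the two paths together at 1e-10. Convergence is declared when the
maximum relative change of cycle-mean volumes between consecutive cycles
falls below 1e-3; the default runs use 25 cycles (~7 s of CPU), and
volume drift over a run is at the 1e-14 level. Initial volumes are
distributed as unstressed plus compliance-proportional stressed volume.

## Flow-metric kernels

All kernels operate on a uniform Cartesian grid with an in-domain mask;
wall faces (mask boundary) carry outward normals and face areas. This
deliberately replaces an unstructured CFD mesh: every kernel then has an
exact analytic fixture (Couette, plug flow, rigid rotation, …), which is
the whole acceptance surface at desk scale.

- **Velocity gradient**: second-order central differences where both
  neighbors are in-domain, one-sided first-order at mask boundaries,
  zero (with a warning) for isolated cells.
- **Strain rate** $\dot\gamma=\sqrt{2S\!:\!S}$ and **Q-criterion**
  $Q=\tfrac12(\|\Omega\|^2-\|S\|^2)$ from the same tensor. The published
  visualisation threshold (325) is stored as a plain number: its printed
  unit does not match Q's dimensions, and the thresholded volume is a
  visual diagnostic, not a risk metric.
- **Carreau viscosity**
  $\eta = \eta_\infty + (\eta_0-\eta_\infty)[1+(\dot\gamma\lambda)^2]^{(N-1)/2}$
  with $\eta_0=0.056$, $\eta_\infty=0.00345$ kg/(m·s), $\lambda=3.313$ s,
  $N=0.3568$, $\rho=1060$ kg/m³.
- **Stagnation volume**: cells with time-averaged velocity < 0.001 m/s
  AND strain rate < 100 1/s. "Time-averaged velocity" is read as the
  magnitude of the time-averaged vector (oscillatory-but-netless flow
  counts as stagnant); a `mean_magnitude` switch implements the other
  convention. The strain-rate bound defaults to the strain rate of the
  time-averaged field, switchable to the time mean of instantaneous
  strain rates.
- **WSS/TAWSS**: wall traction estimated as the local Carreau viscosity
  times the wall-normal gradient of tangential velocity at the first
  in-domain cell (cell center half a spacing from the face, no-slip at
  the wall). Exact for linear profiles, first-order for curved ones —
  the estimator and its convergence order are part of the contract.
  TAWSS bands: < 0.3 Pa low non-physiological, 0.3–9 Pa physiological,
  > 9 Pa high; faces exactly at a bound join the physiological (middle)
  class so the three bands partition the wall.
- **Washout and residence time**: conservative first-order upwind
  transport in advective (divergence-corrected) form with CFL-limited
  sub-stepping (CFL 0.45). Each update is a convex combination of the
  cell and its upwind neighbors, so the washout scalar obeys a maximum
  principle and stays in [0, 1] for any velocity field, including the
  jet/sink source cells. Fresh blood enters through inlet cells held at
  scalar 0; residence time adds a unit source (1 s of age per second)
  and holds the inlet at zero age. Averaging windows default to five
  cycles.

## The synthetic ventricle family

`make_series()` is a surrogate, not a solver. The cavity is an ellipsoid
(semi-axes 30 × 25 × 45 mm, ~142 ml); the flow pattern superposes:

1. a Gaussian inflow jet (peak 1.2 m/s, core radius 6.7 mm) entering
   near the base through a tricuspid-surrogate disc, decaying axially
   over the jet path to the sink;
2. a screened, regularized point sink at the cannula-tip surrogate. The
   tip sits `tip_offset + depth` below the entry plane, so `depth` (5,
   10, 15, 25 mm — the study family) lengthens the inflow-to-tip path,
   and the suction screening length grows with depth
   (`tip_offset/2 + depth + 15 mm`): a deeper tip draws from a broader
   region of the chamber;
3. a solenoidal recirculation cell (curl of a Gaussian vector
   potential, peak 25% of jet speed, center jittered by the seed) that
   carries the zero-mean part of the pulsatility, so the time-averaged
   field is the through-flow pattern alone;
4. a depth-independent basal azimuthal swirl (6% of jet speed),
   emulating the annulus-adjacent rotational flow. Without it, the
   stagnant ring beside the annulus — present at all depths, as the
   study geometry also shows — drifts slightly with tip position and
   can mask the depth trend.

The discrete sink strength is rescaled so the free-region divergence
integrates to zero; a staggered projection (compact 7-point Neumann
Laplacian on the masked cells, sparse Cholesky, nullspace grounded at
one cell) then removes divergence everywhere except the inlet and sink
cells *exactly on the face fluxes*: those mass-conserving fluxes drive
the scalar transport, while cell velocities receive the averaged
face-gradient correction for the tensor kernels. The post-projection
divergence residual (~1e-10 1/s) is recorded in the provenance together
with its bound, $10^{-3}\,U_{peak}/\min h$.

Pulsatility is either the built-in two-peak E/A shape or the tricuspid
inflow exported by the closed-loop model, normalized to unit peak.
Generation is bit-reproducible for a fixed seed and does not disturb the
session RNG.

**What passing tests show — and don't.** On this family, deeper
cannulation monotonically reduces stagnation volume (3.7 → 0.7 ml with
the built-in waveform; 11.2 → 3.4 ml with the exported inflow, a 70–81%
reduction) and the residual old-blood fraction, and raises cycle-mean
kinetic energy — the directional findings the method probes. The
magnitudes are *not* those of a patient-specific CFD: there is no
Navier–Stokes solve, no turbulence, no moving wall, no real cannula
geometry, and the washout of the surrogate is slower than the published
patient case. Tests passing here validate the metric kernels and the
direction of the depth effect, nothing more.

## Numerical choices and degenerate inputs

- Grids: default 32³ (1% voxelization error on the cavity volume);
  kernel oracles run on ≤ 32³ grids, transport fixtures on 64-cell
  channels. The trend suite and pipeline tests use 16³ cases where only
  structure, not magnitude, is asserted.
- The voxelized wall area tends to 3/2 × the smooth surface area (the
  staircase/projected-area limit), so area comparisons test that ratio.
- Ties: valve closed at zero pressure difference; TAWSS band bounds
  belong to the middle class; stagnation thresholds are strict
  inequalities.
- A stopped pump (speed 0) is treated as a clamped branch rather than a
  free-wheeling leak, so the healthy baseline preset ejects through its
  valves.
- Degenerate masks: isolated cells get zero gradients with a warning;
  an empty inlet set is an error; a silent inflow waveform produces an
  identically zero series.
- Interpolated line profiles flag samples whose trilinear stencil
  leaves the mask as missing rather than extrapolating.

## Known limitations

The 0-D model has no baroreflex, no autoregulation, and no left-valve
fluid mechanics beyond the diode law; the supplementary compartment
values are a calibrated fallback rather than a transcription, so
off-design parameter sweeps (e.g., speed ramps far from 4300/5400 RPM)
inherit the calibration's assumptions. The synthetic flow has no
pressure field and no wall motion; TAWSS magnitudes on the ellipsoid
wall are far below cannula-wall values in the published CFD and are only
meaningful relative to the analytic fixtures. The first-order upwind
transport is diffusive; the scheme order is the price of an unconditional
maximum principle at desk scale.
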