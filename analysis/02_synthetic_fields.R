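#!/usr/bin/env Rscript
# Synthetic ventricle-like velocity fields per cannulation depth.
#
# Generates the pulsatile jet/sink/recirculation surrogate flow for each
# cannulation-depth surrogate (5, 10, 15, 25 mm), modulated by the
# tricuspid inflow exported in step 01 (falls back to the built-in E/A
# shape if step 01 has not been run), and writes each series in the
# legacy-VTK + JSON sidecar layout.

library(rvadflow)

depths <- c(0.005, 0.010, 0.015, 0.025)
waves <- if (file.exists("results/waveforms.csv")) {
  cat("using the exported tricuspid inflow as pulsatility\n")
  lpm_read_waveforms("results/waveforms.csv")
} else {
  cat("results/waveforms.csv not found; using the built-in E/A shape\n")
  NULL
}

for (d in depths) {
  p <- synthetic_case_params(depth = d, waveform = waves, seed = 1)
  s <- make_series(p)
  out <- sprintf("results/fields_depth_%02.0fmm", d * 1000)
  write_field_series(s, out)
  cat(sprintf(
    "depth %4.0f mm: sink flux %.3g m^3/s, divergence residual %.2e (bound %.2e) -> %s\n",
    d * 1000, s$provenance$sink_strength_m3s,
    s$provenance$divergence_residual, s$provenance$divergence_bound, out))
}
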