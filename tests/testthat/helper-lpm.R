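# Memoized reference simulations shared across test files (the full
# BiVAD-supported run at the study step size is the expensive fixture).
.lpm_cache <- new.env(parent = emptyenv())

default_bivad_traj <- function() {
  if (is.null(.lpm_cache$traj)) {
    .lpm_cache$traj <- lpm_simulate(lpm_params(), n_cycles = 25, dt = 2e-4)
  }
  .lpm_cache$traj
}

default_bivad_summary <- function() {
  if (is.null(.lpm_cache$summary)) {
    .lpm_cache$summary <- lpm_summarize(default_bivad_traj())
  }
  .lpm_cache$summary
}

# count the interior local maxima of a periodic waveform, ignoring
# sub-threshold ripple
count_peaks <- function(x, frac = 0.05) {
  pk <- which(diff(sign(diff(x))) == -2) + 1L
  length(pk[x[pk] > frac * max(x)])
}
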