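# Shared fixtures built in code.

# PSD with a Gaussian bump (linear power) on a constant background.
gauss_bump_psd <- function(center = 25, sd = 2, height = 1, background = 0,
                           freqs = seq(3, 70, 0.5)) {
  site_psd(freqs, background + height * exp(-(freqs - center)^2 / (2 * sd^2)),
           norm_state = "freq_norm")
}

# Exact power-law spectrum on the standard 0.5 Hz grid.
power_law_psd <- function(offset = 2, alpha = 1.5, freqs = seq(3, 70, 0.5)) {
  site_psd(freqs, 10^(offset - alpha * log10(freqs)))
}

# Small study used by several integration tests: 2 patients x 1 trajectory,
# short subregions to keep site counts low.
small_study <- function(n_patients = 2, seed = 421) {
  set.seed(seed)
  simulate_study(study_config(
    n_patients = n_patients, n_trajectories = 1,
    subregion_lengths = c(pre = 4, motor = 1.5, nonmotor = 1.5)))
}
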