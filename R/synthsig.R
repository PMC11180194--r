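#' Configuration for the Brown-noise / beta / spiking signal simulations
#'
#' Defaults follow the study conditions: 8192 samples at 4096 Hz (a 2-s
#' signal whose middle second is retained after edge trimming), a 20 Hz beta
#' sine at 0.5x (low) or 1.2x (high) the noise SD, a 60th-percentile spike
#' threshold, a Poisson mean of 6 spikes per beta peak, and spike amplitude
#' 3x the maximum of the high-amplitude beta term.
#'
#' @param n_samples Samples generated before edge trimming.
#' @param fs Sampling rate in Hz.
#' @param beta_freq Beta sine frequency (Hz).
#' @param beta_amp_factor Beta amplitude as a multiple of the noise SD.
#' @param spike_rate_mean Poisson mean spike count per beta peak.
#' @param spike_threshold_pct Percentile (0-100) of the high-amplitude beta
#'   sine used as spike threshold.
#' @param spike_amp_factor Spike amplitude as a multiple of max(high beta).
#' @param hp_cutoff High-pass cutoff applied to the Brown noise (Hz).
#' @return A `sim_signal_config` list.
#' @export
sim_signal_config <- function(n_samples = 8192, fs = 4096, beta_freq = 20,
                              beta_amp_factor = 0.5, spike_rate_mean = 6,
                              spike_threshold_pct = 60, spike_amp_factor = 3,
                              hp_cutoff = 0.1) {
  stopifnot(n_samples > 0, fs > 0, fs > 2 * beta_freq,
            beta_amp_factor >= 0, spike_rate_mean >= 0,
            spike_threshold_pct > 0, spike_threshold_pct < 100,
            spike_amp_factor > 0, hp_cutoff > 0, hp_cutoff < fs / 2)
  structure(list(n_samples = as.integer(n_samples), fs = fs,
                 beta_freq = beta_freq, beta_amp_factor = beta_amp_factor,
                 spike_rate_mean = spike_rate_mean,
                 spike_threshold_pct = spike_threshold_pct,
                 spike_amp_factor = spike_amp_factor, hp_cutoff = hp_cutoff),
            class = "sim_signal_config")
}

# Brown noise = cumulative sum of unit Gaussian increments, causally
# high-pass filtered (emulating the hardware 0.1 Hz filter), then trimmed of
# its first and last quarter so filter transients are discarded. Returns the
# retained middle half (n_samples/2 samples).
brown_noise_trimmed <- function(cfg) {
  n <- cfg$n_samples
  x <- cumsum(stats::rnorm(n))
  hp <- butter_sos(2, cfg$hp_cutoff, cfg$fs, type = "high")
  x <- sos_filter(hp, x)
  trim <- floor(n / 4)
  keep <- (trim + 1):(n - trim)
  list(signal = x[keep], keep = keep)
}

# Beta sine generated at full pre-trim length and trimmed with the noise, so
# the retained phase matches a sine that ran from the start of the record.
beta_sine <- function(cfg, amp, keep) {
  t <- (seq_len(cfg$n_samples) - 1) / cfg$fs
  (amp * sin(2 * pi * cfg$beta_freq * t))[keep]
}

#' Simulate Brown noise with beta modulation and its rectified variant
#'
#' Generates Brown noise (cumulative Gaussian increments, 0.1 Hz high-pass,
#' edge quarters discarded), adds a beta sine with amplitude
#' `beta_amp_factor * SD(noise)`, and forms the full-wave-rectified,
#' mean-subtracted variant. This is the simulated LFP used to show that
#' rectification does not move the beta center frequency.
#'
#' @param cfg A [sim_signal_config()].
#' @return List with elements `brown`, `beta`, `beta_modulated`,
#'   `rectified_beta_modulated` (each length `n_samples / 2`), plus `fs`.
#' @export
simulate_brown_beta <- function(cfg = sim_signal_config()) {
  stopifnot(inherits(cfg, "sim_signal_config"))
  bn <- brown_noise_trimmed(cfg)
  x <- bn$signal
  beta <- beta_sine(cfg, cfg$beta_amp_factor * stats::sd(x), bn$keep)
  bm <- x + beta
  rect <- abs(bm) - mean(abs(bm))
  list(brown = x, beta = beta, beta_modulated = bm,
       rectified_beta_modulated = rect, fs = cfg$fs)
}

# Contiguous runs of TRUE in a logical vector -> list of index ranges.
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  Map(function(s, e) s:e, starts[keep], ends[keep])
}

#' Simulate spiking activity riding on beta peaks
#'
#' A high-amplitude (1.2x SD) beta sine is added to Brown noise to form the
#' "membrane potential". Where the membrane signal exceeds the spike
#' threshold (the 60th percentile of the high-amplitude beta sine), a
#' Poisson-distributed number of spikes (mean `spike_rate_mean` per
#' supra-threshold region, i.e. per beta peak) is placed uniformly on the
#' sample grid. Spikes of amplitude `spike_amp_factor * max(beta)` are added,
#' the sum is band-passed 300-2000 Hz (6th-order Butterworth) and full-wave
#' rectified.
#'
#' @param cfg A [sim_signal_config()]; its `beta_amp_factor` is ignored here
#'   (the membrane beta amplitude is fixed at 1.2x SD).
#' @param spk_band Band-pass edges for the spiking band (Hz).
#' @return List with `membrane`, `spike_train` (0/1 indicator),
#'   `with_spikes`, `bandpassed`, `rectified_spk`, `fs`, `n_spikes`,
#'   `n_regions`, and `empty_spike_train` flag.
#' @export
simulate_spiking <- function(cfg = sim_signal_config(), spk_band = c(300, 2000)) {
  stopifnot(inherits(cfg, "sim_signal_config"))
  bn <- brown_noise_trimmed(cfg)
  x <- bn$signal
  hi_beta <- beta_sine(cfg, 1.2 * stats::sd(x), bn$keep)
  membrane <- x + hi_beta
  threshold <- stats::quantile(hi_beta, cfg$spike_threshold_pct / 100,
                               names = FALSE, type = 7)
  spikes <- numeric(length(membrane))
  # One Poisson draw per beta peak: supra-threshold samples are grouped by
  # beta cycle, so noise-induced fragmentation of a peak's crossing does not
  # multiply the draws. Spikes are placed uniformly (without replacement) on
  # the supra-threshold samples of the cycle.
  supra <- which(membrane > threshold)
  regions <- if (length(supra)) {
    cycle <- floor(cfg$beta_freq * (supra - 1) / cfg$fs)
    unname(split(supra, cycle))
  } else list()
  for (idx in regions) {
    k <- min(stats::rpois(1, cfg$spike_rate_mean), length(idx))
    if (k > 0) spikes[idx[sample.int(length(idx), k)]] <- 1
  }
  with_spikes <- membrane + spikes * cfg$spike_amp_factor * max(hi_beta)
  bp <- butter_sos(6, spk_band, cfg$fs, type = "pass")
  bandpassed <- sos_filtfilt(bp, with_spikes)
  rect <- abs(bandpassed)
  list(membrane = membrane, spike_train = spikes, with_spikes = with_spikes,
       bandpassed = bandpassed, rectified_spk = rect, fs = cfg$fs,
       n_spikes = sum(spikes), n_regions = length(regions),
       empty_spike_train = sum(spikes) == 0)
}

#' Average log-PSD over repeated simulation realizations
#'
#' Runs `sim_fun()` `n_rep` times, computes a Hamming-window periodogram of
#' the requested component of each realization, and averages the log10
#' spectra. The returned power is the geometric mean across realizations
#' (i.e. `10^mean(log10 PSD)`), matching the averaged simulation spectra.
#'
#' @param sim_fun Zero-argument function returning a realization list.
#' @param component Name of the list element to analyze.
#' @param n_rep Number of realizations.
#' @param fs Sampling rate (Hz).
#' @param fmax Highest frequency retained (Hz).
#' @return A `site_psd` (geometric-mean power).
#' @export
average_sim_psd <- function(sim_fun, component, n_rep = 1000, fs = 4096,
                            fmax = 200) {
  acc <- NULL
  freqs <- NULL
  for (i in seq_len(n_rep)) {
    xs <- sim_fun()
    p <- periodogram_psd(xs[[component]], fs = fs, fmax = fmax)
    lp <- log10(pmax(p$power, .Machine$double.xmin))
    if (is.null(acc)) { acc <- lp; freqs <- p$freqs } else acc <- acc + lp
  }
  site_psd(freqs, 10^(acc / n_rep), "raw",
           meta = list(n_rep = n_rep, component = component))
}

#' Configuration for the simulated test spectra
#'
#' Grid used to probe how the aperiodic exponent, additive noise, and
#' periodic peaks shape the goodness of fit of the spectral parameterization.
#' Defaults reproduce the study grid: exponents -0.25 to 2.25, offset equal
#' to the exponent, target mean-absolute-error 0.005 to 0.145, 20 repeats per
#' cell, 3-70 Hz, and (optionally) three Gaussian peaks of
#' (18, 5, 1.5), (25, 8, 3) and (35, 5, 2) (center Hz, SD Hz, log10-power).
#'
#' @param exponent_grid Aperiodic exponents to simulate.
#' @param peaks NULL, or a matrix/data.frame with columns center, sd, height.
#' @param noise_mae_grid Target mean absolute deviations of the added noise.
#' @param n_repeats Spectra per grid cell.
#' @param freq_range Frequency range (Hz), 0.5 Hz grid.
#' @return A `spectrum_sim_config` list.
#' @export
spectrum_sim_config <- function(exponent_grid = seq(-0.25, 2.25, by = 0.25),
                                peaks = NULL,
                                noise_mae_grid = seq(0.005, 0.145, by = 0.02),
                                n_repeats = 20, freq_range = c(3, 70)) {
  stopifnot(length(exponent_grid) > 0, n_repeats >= 1,
            all(noise_mae_grid >= 0))
  if (!is.null(peaks)) {
    peaks <- as.data.frame(peaks)
    names(peaks) <- c("center", "sd", "height")
    stopifnot(all(peaks$center >= freq_range[1] & peaks$center <= freq_range[2]))
  }
  structure(list(exponent_grid = exponent_grid, peaks = peaks,
                 noise_mae_grid = noise_mae_grid, n_repeats = n_repeats,
                 freq_range = freq_range),
            class = "spectrum_sim_config")
}

#' The three periodic test peaks used in the goodness-of-fit simulation
#' @return data.frame with columns center, sd, height.
#' @export
test_spectra_peaks <- function() {
  data.frame(center = c(18, 25, 35), sd = c(5, 8, 5), height = c(1.5, 3, 2))
}

gaussian_sum <- function(freqs, peaks) {
  g <- numeric(length(freqs))
  if (is.null(peaks) || nrow(peaks) == 0) return(g)
  for (i in seq_len(nrow(peaks))) {
    g <- g + peaks$height[i] *
      exp(-(freqs - peaks$center[i])^2 / (2 * peaks$sd[i]^2))
  }
  g
}

#' Simulate log-linear test spectra with known ground truth
#'
#' Each spectrum is linear in log-log coordinates,
#' `log10 P(f) = b - alpha * log10 f` with the offset set equal to the
#' exponent (`b = alpha`), optionally plus Gaussian peaks in log-power.
#' Gaussian noise is added and rescaled so its realized mean absolute value
#' equals the requested target exactly.
#'
#' @param cfg A [spectrum_sim_config()].
#' @return List with `freqs` and `cells`: one entry per (exponent, noise)
#'   combination holding `exponent`, `offset`, `target_mae`, `peaks`, and a
#'   `n_repeats x nfreq` matrix `log_power`.
#' @export
simulate_test_spectra <- function(cfg = spectrum_sim_config()) {
  stopifnot(inherits(cfg, "spectrum_sim_config"))
  freqs <- seq(cfg$freq_range[1], cfg$freq_range[2], by = 0.5)
  pk <- gaussian_sum(freqs, cfg$peaks)
  cells <- list()
  for (a in cfg$exponent_grid) {
    base <- a - a * log10(freqs) + pk
    for (tm in cfg$noise_mae_grid) {
      mat <- matrix(NA_real_, cfg$n_repeats, length(freqs))
      for (r in seq_len(cfg$n_repeats)) {
        eps <- stats::rnorm(length(freqs))
        if (tm > 0) eps <- eps * (tm / mean(abs(eps))) else eps <- 0 * eps
        mat[r, ] <- base + eps
      }
      cells[[length(cells) + 1L]] <-
        list(exponent = a, offset = a, target_mae = tm, peaks = cfg$peaks,
             log_power = mat)
    }
  }
  list(freqs = freqs, cells = cells)
}
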