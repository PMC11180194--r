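#' Split a wide-band recording into LFP and SPK streams
#'
#' LFP: zero-phase 4th-order Butterworth band-pass (default 3-200 Hz).
#' SPK: zero-phase 4th-order Butterworth band-pass (default 300-6000 Hz),
#' then full-wave rectified and mean-subtracted, so its low-frequency
#' content reflects the multi-unit discharge rate. The 300-6000 Hz default
#' requires `fs > 12 kHz`; narrow `spk_band` for lower sampling rates.
#'
#' @param x Numeric wide-band signal.
#' @param fs Sampling rate in Hz.
#' @param lfp_band,spk_band Band edges in Hz.
#' @return List with `lfp` and `spk` numeric vectors.
#' @export
split_streams <- function(x, fs, lfp_band = c(3, 200), spk_band = c(300, 6000)) {
  lfp <- sos_filtfilt(butter_sos(4, lfp_band, fs, "pass"), x)
  spk_raw <- sos_filtfilt(butter_sos(4, spk_band, fs, "pass"), x)
  spk <- abs(spk_raw)
  spk <- spk - mean(spk)
  list(lfp = lfp, spk = spk)
}

#' Root-mean-square amplitude of a signal
#' @param x Non-empty numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  if (length(x) == 0) stop("empty signal")
  sqrt(mean(x^2))
}

#' Normalize trajectory site RMS values to the pre-STN baseline
#'
#' Divides each site's RMS by the mean RMS of the first `n_baseline` sites
#' (presumed white-matter baseline). Sites flagged as outliers among the
#' first `n_baseline` are dropped from the baseline mean.
#'
#' @param rms_values Ordered site RMS values along one trajectory.
#' @param n_baseline Number of leading baseline sites (default 10).
#' @param outlier Optional logical vector; baseline uses non-outlier members.
#' @return Numeric NRMS values.
#' @export
normalize_rms <- function(rms_values, n_baseline = 10, outlier = NULL) {
  if (length(rms_values) < n_baseline) {
    stop("need at least ", n_baseline, " sites to form the baseline")
  }
  base <- rms_values[seq_len(n_baseline)]
  if (!is.null(outlier)) base <- base[!outlier[seq_len(n_baseline)]]
  m <- mean(base)
  if (!is.finite(m) || m <= 0) stop("non-positive baseline RMS")
  rms_values / m
}

#' Flag outlier sites by the 3-IQR fence
#'
#' A value is an outlier when it lies more than 3 interquartile ranges above
#' the upper quartile or below the lower quartile. Quartiles use linear
#' interpolation (type 7) so fences are reproducible. Applied per trajectory
#' per stream.
#'
#' @param values Numeric vector (>= 4 values to define quartiles).
#' @param k Fence multiplier (default 3).
#' @return Logical vector of outlier flags.
#' @export
flag_outliers <- function(values, k = 3) {
  if (length(values) < 4) stop("need >= 4 values to define quartiles")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values > q[2] + k * iqr | values < q[1] - k * iqr
}
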