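#' Construct a site power-spectral-density object
#'
#' Light S3 carrier used throughout the pipeline. `norm_state` tracks which
#' normalization has been applied: `raw` (density as estimated), `freq_norm`
#' (divided by total 3-200 Hz power), `freq_dist_norm` (z-scored against the
#' pre-STN baseline per bin), or `whitened`.
#'
#' @param freqs Frequency grid in Hz (uniform spacing).
#' @param power Power per bin, same length as `freqs`.
#' @param norm_state Normalization state string.
#' @param stream `"LFP"`, `"SPK"`, or `NA`.
#' @param meta Named list of site metadata (trajectory, site index, depth...).
#' @return An object of class `site_psd`.
#' @export
site_psd <- function(freqs, power, norm_state = "raw", stream = NA_character_,
                     meta = list()) {
  stopifnot(length(freqs) == length(power))
  structure(list(freqs = as.numeric(freqs), power = as.numeric(power),
                 norm_state = norm_state, stream = stream, meta = meta),
            class = "site_psd")
}

#' @export
print.site_psd <- function(x, ...) {
  cat("<site_psd> ", length(x$freqs), " bins, ",
      min(x$freqs), "-", max(x$freqs), " Hz (",
      x$freqs[2] - x$freqs[1], " Hz spacing), state: ", x$norm_state,
      if (!is.na(x$stream)) paste0(", stream: ", x$stream), "\n", sep = "")
  invisible(x)
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))

one_sided_density <- function(X, fs, wnorm, nfft) {
  p <- (Mod(X)^2) / (fs * wnorm)
  nkeep <- floor(nfft / 2) + 1L
  p <- p[seq_len(nkeep)]
  # double all interior bins (DC and, for even nfft, Nyquist are unique)
  idx <- 2:(nkeep - if (nfft %% 2 == 0) 1L else 0L)
  p[idx] <- 2 * p[idx]
  p
}

#' Welch power spectral density
#'
#' Averaged modified periodograms with a Hamming window and fractional
#' overlap. The default 2-s window gives a 0.5 Hz frequency grid. Sites
#' shorter than 1.5 x the window are not estimable and return an "excluded"
#' object (`$excluded = TRUE`) rather than an error, so upstream bookkeeping
#' can count them.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz); must satisfy `fs >= 2 * fmax`.
#' @param window_s Window length in seconds (default 2).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param fmax Highest frequency retained (Hz, default 200).
#' @param detrend `"none"` (default) or `"constant"` per-segment detrending.
#' @param stream,meta Passed to [site_psd()].
#' @return A `site_psd` with `norm_state = "raw"`.
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5, fmax = 200,
                      detrend = c("none", "constant"),
                      stream = NA_character_, meta = list()) {
  detrend <- match.arg(detrend)
  if (fs < 2 * fmax) stop("fs = ", fs, " Hz cannot resolve fmax = ", fmax, " Hz")
  nwin <- round(window_s * fs)
  if (length(x) < 1.5 * nwin) {
    out <- site_psd(numeric(0), numeric(0), "raw", stream, meta)
    out$excluded <- TRUE
    out$exclude_reason <- "duration < 1.5 x window"
    return(out)
  }
  w <- hamming_window(nwin)
  wnorm <- sum(w^2)
  hop <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)]
    if (detrend == "constant") seg <- seg - mean(seg)
    acc <- acc + one_sided_density(stats::fft(seg * w), fs, wnorm, nwin)
  }
  p <- acc / length(starts)
  freqs <- seq(0, floor(nwin / 2)) * fs / nwin
  keep <- freqs <= fmax
  out <- site_psd(freqs[keep], p[keep], "raw", stream, meta)
  out$excluded <- FALSE
  out$n_segments <- length(starts)
  out
}

#' Single-window periodogram PSD
#'
#' One Hamming-windowed periodogram (optionally zero-padded to `nfft`), as
#' used for the averaged simulation spectra.
#'
#' @inheritParams welch_psd
#' @param nfft FFT length (default: signal length).
#' @return A `site_psd` with `norm_state = "raw"`.
#' @export
periodogram_psd <- function(x, fs, nfft = length(x), fmax = fs / 2,
                            stream = NA_character_, meta = list()) {
  n <- length(x)
  stopifnot(nfft >= n)
  w <- hamming_window(n)
  xw <- c(x * w, rep(0, nfft - n))
  p <- one_sided_density(stats::fft(xw), fs, sum(w^2), nfft)
  freqs <- seq(0, floor(nfft / 2)) * fs / nfft
  keep <- freqs <= fmax
  site_psd(freqs[keep], p[keep], "raw", stream, meta)
}

#' Magnitude-squared coherence between two simultaneous signals
#'
#' Welch-type estimator with a 2-s Hamming window and 50% overlap:
#' `|<Sxy>|^2 / (<Sxx> <Syy>)`, reported on the 3-70 Hz range. Values lie in
#' `[0, 1]`; with few averaged segments the estimator has a known positive
#' bias under independence (~1/L for L segments).
#'
#' @param x,y Equal-length signals recorded simultaneously.
#' @param fs Sampling rate in Hz.
#' @param window_s,overlap Welch segmentation parameters.
#' @param band Frequency range retained (Hz).
#' @return A data.frame with columns `freq` and `coherence`, or `NULL` if the
#'   signals are shorter than 1.5 x the window.
#' @export
mscoherence <- function(x, y, fs, window_s = 2, overlap = 0.5, band = c(3, 70)) {
  stopifnot(length(x) == length(y))
  nwin <- round(window_s * fs)
  if (length(x) < 1.5 * nwin) return(NULL)
  w <- hamming_window(nwin)
  hop <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  nkeep <- floor(nwin / 2) + 1L
  sxx <- syy <- numeric(nkeep)
  sxy <- complex(real = numeric(nkeep), imaginary = numeric(nkeep))
  for (s in starts) {
    X <- stats::fft(x[s:(s + nwin - 1L)] * w)[seq_len(nkeep)]
    Y <- stats::fft(y[s:(s + nwin - 1L)] * w)[seq_len(nkeep)]
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  coh <- Mod(sxy)^2 / (sxx * syy)
  freqs <- seq(0, floor(nwin / 2)) * fs / nwin
  keep <- freqs >= band[1] & freqs <= band[2]
  data.frame(freq = freqs[keep], coherence = pmin(coh[keep], 1))
}
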