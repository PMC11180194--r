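#' Whiten a PSD in the frequency domain
#'
#' Removes the aperiodic 1/f^alpha trend by multiplying each bin's power by
#' its frequency raised to alpha: `p_w(f) = p_o(f) * f^alpha`, where alpha
#' is the site's fitted aperiodic exponent. Linear in the input and exactly
#' invertible (divide by `f^alpha`). Restricted to the 3-70 Hz support used
#' for the exponent fit.
#'
#' @param psd A `site_psd`.
#' @param alpha Aperiodic exponent fitted on the same site and stream.
#' @param band Frequency support retained (Hz).
#' @return `site_psd` with `norm_state = "whitened"`, carrying `alpha_used`
#'   and `method = "frequency_domain"`.
#' @export
whiten_frequency <- function(psd, alpha, band = c(3, 70)) {
  stopifnot(inherits(psd, "site_psd"), is.finite(alpha))
  sel <- psd$freqs >= band[1] & psd$freqs <= band[2]
  f <- psd$freqs[sel]
  psd$power <- psd$power[sel] * f^alpha
  psd$freqs <- f
  psd$norm_state <- "whitened"
  psd$alpha_used <- alpha
  psd$method <- "frequency_domain"
  psd
}

#' Whiten a signal in the time domain
#'
#' The signal is multiplied by an n-point symmetric Hann window, Fourier
#' transformed, and the spectral magnitudes inside `band` are scaled by
#' `f^alpha` with phases preserved; magnitudes outside the band (including
#' DC) are zeroed so the frequency support matches the frequency-domain
#' path. The inverse transform gives the whitened signal, from which a
#' Welch PSD is re-estimated. `alpha` should come from a spectral
#' parameterization of the magnitude spectrum (use
#' [fit_magnitude_exponent()]).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param alpha Aperiodic exponent of the magnitude spectrum.
#' @param band Frequency band retained and whitened (Hz).
#' @param window_s Welch window for the re-estimated PSD (s).
#' @return List: `signal` (whitened time series) and `psd` (a `site_psd`
#'   with `method = "time_domain"`), or excluded marker when too short.
#' @export
whiten_time <- function(x, fs, alpha, band = c(3, 70), window_s = 2) {
  n <- length(x)
  if (n < fs / band[1]) {
    return(list(signal = NULL, psd = NULL, excluded = TRUE,
                exclude_reason = "too short for 3 Hz resolution"))
  }
  xw <- x * hann_window(n)
  X <- stats::fft(xw)
  # two-sided frequency per bin (negative frequencies mirror positive)
  f <- seq(0, n - 1) * fs / n
  f[f > fs / 2] <- f[f > fs / 2] - fs
  af <- abs(f)
  scale <- numeric(n)
  inband <- af >= band[1] & af <= band[2]
  scale[inband] <- af[inband]^alpha
  Xw <- X * scale
  xwh <- Re(stats::fft(Xw, inverse = TRUE)) / n
  psd <- welch_psd(xwh, fs, window_s = window_s, fmax = band[2])
  if (!isTRUE(psd$excluded)) {
    sel <- psd$freqs >= band[1]
    psd$freqs <- psd$freqs[sel]
    psd$power <- psd$power[sel]
    psd$norm_state <- "whitened"
    psd$alpha_used <- alpha
    psd$method <- "time_domain"
  }
  list(signal = xwh, psd = psd, excluded = FALSE)
}

#' Fit the aperiodic exponent of a signal's magnitude spectrum
#'
#' Time-domain whitening scales spectral magnitudes, so its alpha is fitted
#' on the magnitude (not power) spectrum: the Hann-windowed FFT magnitude is
#' passed through [fit_spectrum()] as if it were power.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param settings A [fit_settings()].
#' @return The fitted exponent (numeric scalar).
#' @export
fit_magnitude_exponent <- function(x, fs, settings = fit_settings()) {
  n <- length(x)
  X <- stats::fft(x * hann_window(n))
  nkeep <- floor(n / 2) + 1L
  mag <- Mod(X)[seq_len(nkeep)]
  freqs <- seq(0, floor(n / 2)) * fs / n
  sel <- freqs >= settings$fit_range[1] & freqs <= settings$fit_range[2]
  fit <- fit_spectrum(pmax(mag[sel], .Machine$double.xmin), settings,
                      freqs = freqs[sel])
  fit$exponent
}
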