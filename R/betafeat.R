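#' Detect the beta center frequency of a whitened/normalized PSD
#'
#' The beta center frequency (betaCF) is the frequency of the highest local
#' peak (strictly greater than both neighbors) inside the beta band. When no
#' local maximum exists in the band, a no-peak result is returned — a valid
#' outcome excluded from paired analyses, not an error.
#'
#' @param psd A `site_psd` (typically whitened and/or distance-normalized),
#'   or a numeric power vector with `freqs` supplied.
#' @param band Beta search band in Hz (default 13-33).
#' @param freqs Frequency grid when `psd` is a bare vector.
#' @return List of class `beta_peak`: `beta_cf`, `peak_power`,
#'   `has_peak`.
#' @export
detect_beta_cf <- function(psd, band = c(13, 33), freqs = NULL) {
  if (inherits(psd, "site_psd")) {
    freqs <- psd$freqs
    power <- psd$power
  } else {
    power <- as.numeric(psd)
    if (is.null(freqs)) stop("freqs required")
  }
  n <- length(power)
  cand <- which(freqs >= band[1] & freqs <= band[2])
  cand <- cand[cand > 1 & cand < n]
  is_local <- power[cand] > power[cand - 1] & power[cand] > power[cand + 1]
  cand <- cand[is_local]
  if (!length(cand)) {
    return(structure(list(beta_cf = NA_real_, peak_power = NA_real_,
                          has_peak = FALSE), class = "beta_peak"))
  }
  best <- cand[which.max(power[cand])]
  structure(list(beta_cf = freqs[best], peak_power = power[best],
                 has_peak = TRUE), class = "beta_peak")
}

#' Shift a PSD (or spectrogram) frequency axis to its beta center frequency
#'
#' Translates the frequency axis by `-beta_cf`, so DeltaFrequency = 0 marks
#' the beta peak. Used to separate single-site peak width from the
#' population dispersion of center frequencies.
#'
#' @param x A `site_psd` or `trajectory_spectrogram`.
#' @param beta_cf The detected beta center frequency (Hz).
#' @return The same object with a translated `freqs` axis and an `aligned`
#'   flag.
#' @export
align_to_cf <- function(x, beta_cf) {
  stopifnot(is.finite(beta_cf))
  x$freqs <- x$freqs - beta_cf
  x$aligned <- TRUE
  x
}

# Topographic (findpeaks-style) prominence of the peak at index i: descend
# on each side until a higher point (or the edge) is met; the higher of the
# two interval minima is the saddle; prominence = height - saddle.
peak_prominence <- function(power, i) {
  v <- power[i]
  left <- if (i > 1) power[seq_len(i - 1)] else numeric(0)
  right <- if (i < length(power)) power[(i + 1):length(power)] else numeric(0)
  base_side <- function(seg, from_peak) {
    if (!length(seg)) return(-Inf)
    higher <- which(seg > v)
    if (from_peak == "left") {
      seg <- if (length(higher)) seg[(max(higher) + 1):length(seg)] else seg
    } else {
      seg <- if (length(higher)) seg[seq_len(min(higher) - 1)] else seg
    }
    if (!length(seg)) return(v)
    min(seg)
  }
  lmin <- base_side(left, "left")
  rmin <- base_side(right, "right")
  v - max(lmin, rmin)
}

# Find the frequency where power crosses `ref` walking outward from the
# peak; linear interpolation between the bracketing bins. Returns NA when
# the flank never crosses within the grid (censored).
flank_crossing <- function(freqs, power, ipk, ref, direction) {
  idx <- if (direction == "left") rev(seq_len(ipk - 1)) else (ipk + 1):length(power)
  if (ipk == 1 && direction == "left") return(NA_real_)
  if (ipk == length(power) && direction == "right") return(NA_real_)
  prev <- ipk
  for (i in idx) {
    if (power[i] <= ref) {
      f1 <- freqs[prev]; f2 <- freqs[i]
      p1 <- power[prev]; p2 <- power[i]
      if (p1 == p2) return(f2)
      return(f1 + (ref - p1) * (f2 - f1) / (p2 - p1))
    }
    prev <- i
  }
  NA_real_
}

#' Measure beta-peak bandwidths at half, quarter, and three-quarter height
#'
#' Finds the highest beta peak on a normalized PSD, computes its topographic
#' prominence within the full spectrum, and measures widths at reference
#' heights `peak - prominence/2` (half), `peak - 3/4 prominence` (quarter
#' height) and `peak - prominence/4` (three-quarter height). Flank
#' crossings are located by linear interpolation between the bracketing
#' bins; half-side widths run from the crossing to the peak location. A
#' flank that never crosses within the grid is censored at the range edge
#' and flagged.
#'
#' @param psd A `site_psd` (freq_norm, freq_dist_norm, whitened or aligned).
#' @param band Beta search band (Hz); for aligned spectra centered on 0 use
#'   e.g. `c(-10, 10)`.
#' @return List of class `bandwidth_record`: per level (`half`, `quarter`,
#'   `three_quarter`) the left/right half-side widths and band width, plus
#'   `beta_cf`, `peak_power`, `prominence`, `censored`, `has_peak`.
#' @export
measure_bandwidth <- function(psd, band = c(13, 33)) {
  stopifnot(inherits(psd, "site_psd"))
  pk <- detect_beta_cf(psd, band = band)
  if (!pk$has_peak) {
    return(structure(list(has_peak = FALSE), class = "bandwidth_record"))
  }
  freqs <- psd$freqs
  power <- psd$power
  ipk <- which(freqs == pk$beta_cf)[1]
  prom <- peak_prominence(power, ipk)
  levels <- c(half = 0.5, quarter = 0.75, three_quarter = 0.25)
  out <- list(has_peak = TRUE, beta_cf = pk$beta_cf, peak_power = pk$peak_power,
              prominence = prom, censored = FALSE)
  for (nm in names(levels)) {
    ref <- power[ipk] - levels[[nm]] * prom
    lf <- flank_crossing(freqs, power, ipk, ref, "left")
    rf <- flank_crossing(freqs, power, ipk, ref, "right")
    cens <- is.na(lf) || is.na(rf)
    if (is.na(lf)) lf <- freqs[1]
    if (is.na(rf)) rf <- freqs[length(freqs)]
    out$censored <- out$censored || cens
    out[[paste0(nm, "_left")]] <- pk$beta_cf - lf
    out[[paste0(nm, "_right")]] <- rf - pk$beta_cf
    out[[paste0(nm, "_band_width")]] <- (pk$beta_cf - lf) + (rf - pk$beta_cf)
  }
  structure(out, class = "bandwidth_record")
}

#' Summarize the LFP-to-SPK beta center-frequency downshift
#'
#' Given paired beta center frequencies from the two streams (per trajectory
#' or per site), reports the fractions of pairs where the SPK betaCF is
#' below ("downshift"), above ("upshift"), or within `equal_band` Hz of the
#' LFP betaCF, together with a two-tailed Wilcoxon signed-rank test of the
#' paired difference.
#'
#' @param lfp_cf,spk_cf Paired betaCF vectors (Hz); pairs with `NA` are
#'   dropped.
#' @param equal_band Half-width of the "equal" band (default 0.5 Hz, one
#'   bin).
#' @return List of class `downshift_summary`: `n_pairs`, `fraction_down`,
#'   `fraction_up`, `fraction_equal`, `statistic`, `p_value`.
#' @export
summarize_downshift <- function(lfp_cf, spk_cf, equal_band = 0.5) {
  stopifnot(length(lfp_cf) == length(spk_cf))
  ok <- is.finite(lfp_cf) & is.finite(spk_cf)
  l <- lfp_cf[ok]; s <- spk_cf[ok]
  n <- length(l)
  d <- l - s  # positive = SPK downshifted relative to LFP
  equal <- abs(d) < equal_band
  res <- list(n_pairs = n,
              fraction_down = if (n) mean(d > 0 & !equal) else NA_real_,
              fraction_up = if (n) mean(d < 0 & !equal) else NA_real_,
              fraction_equal = if (n) mean(equal) else NA_real_,
              statistic = NA_real_, p_value = NA_real_)
  if (n >= 2 && any(d != 0)) {
    wt <- suppressWarnings(stats::wilcox.test(l, s, paired = TRUE,
                                              alternative = "two.sided"))
    res$statistic <- unname(wt$statistic)
    res$p_value <- wt$p.value
  }
  structure(res, class = "downshift_summary")
}
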