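#' Repair power-line noise bins in a PSD
#'
#' Bins within `half_width` Hz of the mains frequency and its harmonics (up
#' to the top of the grid) are replaced by the mean of the closest
#' unaffected bin on each side (single-sided at grid edges). Idempotent:
#' repairing twice changes nothing.
#'
#' @param psd A `site_psd` (raw state).
#' @param mains Mains frequency in Hz (default 50).
#' @param half_width Half-width of each notch band in Hz (default 2).
#' @return The repaired `site_psd`.
#' @export
repair_line_noise <- function(psd, mains = 50, half_width = 2) {
  stopifnot(inherits(psd, "site_psd"))
  f <- psd$freqs
  p <- psd$power
  if (!length(f)) return(psd)
  harmonics <- seq(mains, max(f) + half_width, by = mains)
  for (h in harmonics) {
    idx <- which(abs(f - h) <= half_width)
    if (!length(idx)) next
    below <- if (min(idx) > 1) p[min(idx) - 1L] else NA_real_
    above <- if (max(idx) < length(p)) p[max(idx) + 1L] else NA_real_
    repl <- mean(c(below, above), na.rm = TRUE)
    if (is.finite(repl)) p[idx] <- repl
  }
  psd$power <- p
  psd
}

#' Normalize a PSD by its total 3-200 Hz power
#'
#' Each bin is divided by the summed power between `total_range[1]` and
#' `total_range[2]` Hz, so bins read as fraction of total power. Scale
#' invariant; removes the effect of overall amplitude (RMS) changes.
#'
#' @param psd A `site_psd`.
#' @param total_range Range over which total power is summed (Hz).
#' @return `site_psd` with `norm_state = "freq_norm"`.
#' @export
normalize_by_frequency <- function(psd, total_range = c(3, 200)) {
  stopifnot(inherits(psd, "site_psd"))
  sel <- psd$freqs >= total_range[1] & psd$freqs <= total_range[2]
  tot <- sum(psd$power[sel])
  if (!is.finite(tot) || tot <= 0) stop("zero or non-finite total power")
  psd$power <- psd$power / tot
  psd$norm_state <- "freq_norm"
  psd
}

#' Z-score trajectory NPSDs against the pre-STN baseline per frequency bin
#'
#' For each frequency bin, the mean and SD across the first `n_baseline`
#' (pre-STN) sites define the baseline; every site's value is z-scored
#' against them ("normalization by frequency and distance"). Bins with zero
#' baseline SD are set to 0 and flagged.
#'
#' @param psds List of `site_psd` objects (freq_norm state), ordered by
#'   depth, first `n_baseline` being the pre-STN baseline.
#' @param n_baseline Number of baseline sites (default 10).
#' @return List of `site_psd` with `norm_state = "freq_dist_norm"`; each
#'   carries `meta$zero_sd_bins` with the count of degenerate bins.
#' @export
normalize_by_distance <- function(psds, n_baseline = 10) {
  stopifnot(length(psds) >= n_baseline)
  mat <- do.call(rbind, lapply(psds[seq_len(n_baseline)], function(p) p$power))
  mu <- colMeans(mat)
  sd_ <- apply(mat, 2, stats::sd)
  zero <- sd_ <= 0 | !is.finite(sd_)
  if (any(zero)) warning(sum(zero), " frequency bins with zero baseline SD set to 0")
  lapply(psds, function(p) {
    z <- (p$power - mu) / ifelse(zero, 1, sd_)
    z[zero] <- 0
    p$power <- z
    p$norm_state <- "freq_dist_norm"
    p$meta$zero_sd_bins <- sum(zero)
    p
  })
}

#' Assemble a trajectory spectrogram over normalized distance
#'
#' Maps site depths to normalized distance ND = (depth - entry) /
#' (exit - entry), so the STN entry is 0, the exit 1, and pre-STN sites are
#' negative, and stacks the site PSDs into a frequency x distance matrix.
#'
#' @param psds List of `site_psd`, ordered by increasing depth.
#' @param depths_mm Site depths (mm, increasing with penetration).
#' @param entry_mm,exit_mm STN entry and exit depths (mm); `exit_mm` must
#'   exceed `entry_mm`.
#' @return List of class `trajectory_spectrogram`: `nd` (per site), `freqs`,
#'   `power` (freq x site matrix), `norm_state`.
#' @export
build_spectrogram <- function(psds, depths_mm, entry_mm, exit_mm) {
  if (exit_mm <= entry_mm) stop("STN exit depth must exceed entry depth")
  stopifnot(length(psds) == length(depths_mm))
  if (is.unsorted(depths_mm, strictly = TRUE)) stop("depths must be strictly increasing")
  nd <- (depths_mm - entry_mm) / (exit_mm - entry_mm)
  freqs <- psds[[1]]$freqs
  power <- vapply(psds, function(p) p$power, numeric(length(freqs)))
  structure(list(nd = nd, freqs = freqs, power = power,
                 norm_state = psds[[1]]$norm_state),
            class = "trajectory_spectrogram")
}
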