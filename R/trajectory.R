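#' Trajectory inclusion decision
#'
#' A trajectory is analyzable when all three subregions (pre-STN, STN motor,
#' STN non-motor) are present and each spans strictly more than 1 mm.
#'
#' @param depths_mm Site depths (mm).
#' @param subregion Site labels in `{"pre", "motor", "nonmotor"}`.
#' @return List: `accept` (logical) and `reason` (string, `""` on accept).
#' @export
include_trajectory <- function(depths_mm, subregion) {
  need <- c("pre", "motor", "nonmotor")
  missing <- setdiff(need, unique(subregion))
  if (length(missing)) {
    return(list(accept = FALSE,
                reason = paste("missing subregion(s):",
                               paste(missing, collapse = ", "))))
  }
  for (s in need) {
    d <- depths_mm[subregion == s]
    len <- diff(range(d))
    if (!(len > 1)) {
      return(list(accept = FALSE,
                  reason = sprintf("subregion %s spans %.2f mm (<= 1 mm)", s, len)))
    }
  }
  list(accept = TRUE, reason = "")
}

#' Flag sites inside the safe-boundary exclusion zones
#'
#' Subregion borders detected by the upstream classifier are imprecise, so
#' sites within `margin` mm of a border are excluded from subregion-level
#' averages: motor and non-motor lose `margin` at both entry and exit;
#' pre-STN loses only its final `margin` before the STN entry.
#'
#' @param depths_mm Site depths (mm).
#' @param subregion Site labels.
#' @param entry_mm STN entry depth (pre/motor border).
#' @param motor_end_mm Motor/non-motor border depth.
#' @param exit_mm STN exit depth.
#' @param margin Exclusion margin in mm (default 0.5).
#' @return Logical vector: TRUE where the site is boundary-excluded.
#' @export
apply_safe_boundaries <- function(depths_mm, subregion, entry_mm, motor_end_mm,
                                  exit_mm, margin = 0.5) {
  excl <- rep(FALSE, length(depths_mm))
  pre <- subregion == "pre"
  excl[pre] <- depths_mm[pre] > entry_mm - margin
  # retained interval is [border + margin, border - margin], inclusive; a
  # subregion no longer than 2 x margin has a degenerate retained interval
  # and is consumed entirely
  mot <- subregion == "motor"
  excl[mot] <- depths_mm[mot] < entry_mm + margin |
               depths_mm[mot] > motor_end_mm - margin |
               motor_end_mm - entry_mm <= 2 * margin
  nm <- subregion == "nonmotor"
  excl[nm] <- depths_mm[nm] < motor_end_mm + margin |
              depths_mm[nm] > exit_mm - margin |
              exit_mm - motor_end_mm <= 2 * margin
  excl
}

#' Average site PSDs within a subregion
#'
#' Unweighted mean across retained (non-outlier, duration-qualified,
#' non-boundary) sites; `NULL` when no site survives.
#'
#' @param psds List of `site_psd` on a common grid.
#' @param retain Logical vector of sites to include.
#' @return A `site_psd` (mean power) or `NULL`.
#' @export
subregion_average_psd <- function(psds, retain = rep(TRUE, length(psds))) {
  psds <- psds[retain]
  if (!length(psds)) return(NULL)
  p <- rowMeans(vapply(psds, function(x) x$power,
                       numeric(length(psds[[1]]$power))))
  out <- psds[[1]]
  out$power <- p
  out$meta$n_sites <- length(psds)
  out
}

process_trajectory <- function(tj, settings, psd_window_s = 2) {
  ns <- length(tj$depths_mm)
  motor_end <- max(tj$depths_mm[tj$subregion == "motor"])
  inc <- include_trajectory(tj$depths_mm, tj$subregion)
  if (!inc$accept) return(list(accepted = FALSE, reason = inc$reason))
  boundary <- apply_safe_boundaries(tj$depths_mm, tj$subregion, tj$entry_mm,
                                    motor_end, tj$exit_mm)
  out <- list(accepted = TRUE, patient = tj$patient, trajectory = tj$trajectory)
  for (stream in c("lfp", "spk")) {
    sig <- tj[[stream]]
    site_rms <- apply(sig, 2, rms)
    outlier <- flag_outliers(site_rms)
    nrms <- normalize_rms(site_rms, n_baseline = 10, outlier = outlier)
    psds <- vector("list", ns)
    too_short <- rep(FALSE, ns)
    for (k in seq_len(ns)) {
      p <- welch_psd(sig[, k], tj$fs, window_s = psd_window_s, fmax = 200,
                     stream = toupper(stream),
                     meta = list(patient = tj$patient,
                                 trajectory = tj$trajectory, site = k,
                                 depth_mm = tj$depths_mm[k],
                                 subregion = tj$subregion[k]))
      if (isTRUE(p$excluded)) { too_short[k] <- TRUE; psds[[k]] <- p; next }
      psds[[k]] <- normalize_by_frequency(repair_line_noise(p))
    }
    usable <- !too_short & !outlier
    retain <- usable & !boundary
    # per-site aperiodic fits (needed for whitening) and whitened NPSDs
    fits <- vector("list", ns)
    wpsds <- vector("list", ns)
    for (k in which(usable)) {
      fits[[k]] <- fit_spectrum(psds[[k]], settings)
      wpsds[[k]] <- whiten_frequency(psds[[k]], fits[[k]]$exponent,
                                     band = settings$fit_range)
    }
    # z-normalization of whitened NPSDs against the 10 leading pre-STN sites
    base_idx <- which(tj$subregion == "pre")[1:10]
    zpsds <- NULL
    if (all(!is.na(base_idx)) && all(usable[base_idx])) {
      have <- which(usable)
      zpsds <- vector("list", ns)
      mat <- do.call(rbind, lapply(wpsds[base_idx], function(p) p$power))
      mu <- colMeans(mat)
      sd_ <- apply(mat, 2, stats::sd)
      zero <- sd_ <= 0 | !is.finite(sd_)
      for (k in have) {
        z <- wpsds[[k]]
        zv <- (z$power - mu) / ifelse(zero, 1, sd_)
        zv[zero] <- 0
        z$power <- zv
        z$norm_state <- "freq_dist_norm"
        zpsds[[k]] <- z
      }
    }
    subavg <- list()
    subfits <- list()
    for (s in c("pre", "motor", "nonmotor")) {
      sel <- tj$subregion == s & retain
      avg <- subregion_average_psd(psds, sel)
      subavg[[s]] <- avg
      subfits[[s]] <- if (!is.null(avg)) fit_spectrum(avg, settings) else NULL
    }
    motor_sel <- tj$subregion == "motor" & retain
    mavg_w <- subregion_average_psd(wpsds, motor_sel)
    mavg_z <- if (!is.null(zpsds)) {
      ok <- motor_sel & !vapply(zpsds, is.null, logical(1))
      subregion_average_psd(zpsds, ok)
    } else NULL
    out[[stream]] <- list(
      rms = site_rms, nrms = nrms, outlier = outlier, too_short = too_short,
      boundary = boundary, retain = retain, psds = psds, fits = fits,
      whitened = wpsds, z_whitened = zpsds, subregion_avg = subavg,
      subregion_fits = subfits, motor_avg_whitened = mavg_w,
      motor_avg_z = mavg_z,
      counts = c(raw = ns, retained = sum(retain),
                 outlier = sum(outlier & !too_short),
                 too_short = sum(too_short),
                 boundary = sum(boundary & usable)))
  }
  out
}

#' Run the full analysis pipeline over a synthetic (or loaded) study
#'
#' Per trajectory and stream: RMS/NRMS and 3-IQR outlier flags, inclusion
#' criteria, safe-boundary trimming, Welch NPSDs with line-noise repair,
#' per-site spectral-parameterization fits, frequency-domain whitening,
#' pre-STN z-normalization, subregion-averaged PSD fits, and motor-domain
#' beta center frequencies. Across trajectories: LFP-vs-SPK betaCF
#' downshift summaries (frequency-normalized and z-normalized variants) and
#' the two-factor ANOVA of aperiodic parameters.
#'
#' @param study A `synthetic_study` (from [simulate_study()] or
#'   [read_study()]).
#' @param settings A [fit_settings()].
#' @return List of class `pipeline_result`: `fits` (per-trajectory
#'   subregion-fit table), `beta` (per-trajectory betaCF table),
#'   `downshift`, `downshift_z`, `anova_exponent`, `anova_offset`,
#'   `counts`, `rejected`.
#' @export
run_pipeline <- function(study, settings = fit_settings()) {
  stopifnot(inherits(study, "synthetic_study"))
  fits_rows <- list()
  beta_rows <- list()
  counts_rows <- list()
  rejected <- list()
  for (tj in study$trajectories) {
    res <- process_trajectory(tj, settings)
    if (!res$accepted) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(patient = tj$patient, trajectory = tj$trajectory,
                   reason = res$reason)
      next
    }
    for (stream in c("lfp", "spk")) {
      st <- res[[stream]]
      for (s in c("pre", "motor", "nonmotor")) {
        f <- st$subregion_fits[[s]]
        if (is.null(f)) next
        fits_rows[[length(fits_rows) + 1L]] <-
          data.frame(patient = res$patient, trajectory = res$trajectory,
                     stream = toupper(stream), subregion = s,
                     offset = f$offset, exponent = f$exponent,
                     n_peaks = nrow(f$peaks), r_squared = f$r_squared,
                     mae = f$mae, converged = f$converged)
      }
      cf_w <- if (!is.null(st$motor_avg_whitened)) {
        detect_beta_cf(st$motor_avg_whitened)
      } else NULL
      cf_z <- if (!is.null(st$motor_avg_z)) detect_beta_cf(st$motor_avg_z) else NULL
      beta_rows[[length(beta_rows) + 1L]] <-
        data.frame(patient = res$patient, trajectory = res$trajectory,
                   stream = toupper(stream),
                   beta_cf = if (!is.null(cf_w) && cf_w$has_peak) cf_w$beta_cf else NA_real_,
                   beta_cf_z = if (!is.null(cf_z) && cf_z$has_peak) cf_z$beta_cf else NA_real_)
      counts_rows[[length(counts_rows) + 1L]] <-
        data.frame(patient = res$patient, trajectory = res$trajectory,
                   stream = toupper(stream), t(st$counts))
    }
  }
  fits <- do.call(rbind, fits_rows)
  beta <- do.call(rbind, beta_rows)
  counts <- do.call(rbind, counts_rows)
  wide <- merge(beta[beta$stream == "LFP", c("patient", "trajectory", "beta_cf", "beta_cf_z")],
                beta[beta$stream == "SPK", c("patient", "trajectory", "beta_cf", "beta_cf_z")],
                by = c("patient", "trajectory"), suffixes = c("_lfp", "_spk"))
  down <- summarize_downshift(wide$beta_cf_lfp, wide$beta_cf_spk)
  down_z <- summarize_downshift(wide$beta_cf_z_lfp, wide$beta_cf_z_spk)
  an_exp <- tryCatch(anova_aperiodic(fits, "exponent"), error = function(e) NULL)
  an_off <- tryCatch(anova_aperiodic(fits, "offset"), error = function(e) NULL)
  structure(list(fits = fits, beta = beta, beta_pairs = wide,
                 downshift = down, downshift_z = down_z,
                 anova_exponent = an_exp, anova_offset = an_off,
                 counts = counts,
                 rejected = if (length(rejected)) do.call(rbind, rejected) else NULL),
            class = "pipeline_result")
}
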