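#' Settings for the spectral parameterization fit
#'
#' Defaults are the study settings: `peak_width_limits = c(0.8, 12)` Hz
#' (bandwidth, i.e. 2 SD, bounds), the frequency-proportional width bound
#' `peak_width_limits_per = c(0.02, 0)` added to avoid overfitting narrow
#' high-frequency peaks, at most 6 peaks, minimum peak height 0.05
#' log10-power, peak threshold 2 SD of the flattened spectrum, fixed (no
#' knee) aperiodic mode, and a 3-70 Hz fit range.
#'
#' The proportional bound is interpreted as an effective lower bandwidth
#' limit of `max(peak_width_limits[1], peak_width_limits_per[1] * cf)` at
#' center frequency `cf`; a zero second element disables the proportional
#' upper bound. This interpretation is isolated in [effective_width_limits()]
#' so it can be swapped.
#'
#' @param peak_width_limits Bandwidth (FWHM-like, 2 SD) bounds in Hz.
#' @param peak_width_limits_per Proportional (per-Hz) bandwidth bounds.
#' @param max_n_peaks Maximum number of Gaussian peaks.
#' @param min_peak_height Minimum peak height (log10-power).
#' @param peak_threshold Peak detection threshold in SD of the flattened
#'   spectrum.
#' @param aperiodic_mode Only `"fixed"` is supported.
#' @param fit_range Frequency range of the fit (Hz).
#' @return A `fit_settings` list.
#' @export
fit_settings <- function(peak_width_limits = c(0.8, 12),
                         peak_width_limits_per = c(0.02, 0),
                         max_n_peaks = 6, min_peak_height = 0.05,
                         peak_threshold = 2, aperiodic_mode = "fixed",
                         fit_range = c(3, 70)) {
  stopifnot(peak_width_limits[1] > 0, peak_width_limits[2] > peak_width_limits[1],
            max_n_peaks >= 0, min_peak_height >= 0, peak_threshold >= 0)
  aperiodic_mode <- match.arg(aperiodic_mode, "fixed")
  structure(list(peak_width_limits = peak_width_limits,
                 peak_width_limits_per = peak_width_limits_per,
                 max_n_peaks = max_n_peaks, min_peak_height = min_peak_height,
                 peak_threshold = peak_threshold,
                 aperiodic_mode = aperiodic_mode, fit_range = fit_range),
            class = "fit_settings")
}

#' Effective Gaussian width (SD) limits at a given center frequency
#'
#' Combines the absolute bandwidth limits with the frequency-proportional
#' lower bound and converts bandwidth (2 SD) to SD.
#'
#' @param cf Center frequency (Hz).
#' @param settings A [fit_settings()].
#' @return Length-2 numeric: lower and upper SD limits.
#' @export
effective_width_limits <- function(cf, settings) {
  lo_bw <- max(settings$peak_width_limits[1],
               settings$peak_width_limits_per[1] * cf)
  hi_bw <- settings$peak_width_limits[2]
  if (settings$peak_width_limits_per[2] > 0) {
    hi_bw <- min(hi_bw, settings$peak_width_limits_per[2] * cf)
  }
  c(lo_bw, hi_bw) / 2
}

# Linear aperiodic fit in log-log space: log10 P = offset - alpha * log10 f.
simple_ap_fit <- function(logf, logp) {
  fit <- stats::lm.fit(cbind(1, logf), logp)
  c(offset = fit$coefficients[[1]], exponent = -fit$coefficients[[2]])
}

# Robust variant: fit, flatten, zero negative residuals, keep only points at
# or below the 2.5th percentile of the flattened spectrum, refit. This pulls
# the aperiodic fit under the peaks rather than through them.
robust_ap_fit <- function(logf, logp) {
  ap0 <- simple_ap_fit(logf, logp)
  flat <- logp - (ap0[1] - ap0[2] * logf)
  flat[flat < 0] <- 0
  thresh <- stats::quantile(flat, 0.025, names = FALSE, type = 7)
  mask <- flat <= thresh
  if (sum(mask) < 2) mask <- rep(TRUE, length(logf))
  simple_ap_fit(logf[mask], logp[mask])
}

gauss_model <- function(freqs, params) {
  # params: matrix with columns cf, height, sd
  g <- numeric(length(freqs))
  if (is.null(params) || nrow(params) == 0) return(g)
  for (i in seq_len(nrow(params))) {
    g <- g + params[i, 2] * exp(-(freqs - params[i, 1])^2 / (2 * params[i, 3]^2))
  }
  g
}

# Iterative peak guessing on the flattened spectrum: take the tallest point,
# estimate the width from the half-height crossing, subtract, repeat.
guess_peaks <- function(freqs, flat, settings) {
  guesses <- NULL
  work <- flat
  for (k in seq_len(settings$max_n_peaks)) {
    imax <- which.max(work)
    h <- work[imax]
    if (!is.finite(h)) break
    if (h <= settings$peak_threshold * stats::sd(work)) break
    if (h <= settings$min_peak_height) break
    cf <- freqs[imax]
    half <- 0.5 * h
    li <- imax
    while (li > 1 && work[li] > half) li <- li - 1
    ri <- imax
    while (ri < length(work) && work[ri] > half) ri <- ri + 1
    left_ok <- work[li] <= half
    right_ok <- work[ri] <= half
    fres <- freqs[2] - freqs[1]
    short <- if (left_ok && right_ok) {
      min(imax - li, ri - imax)
    } else if (left_ok) imax - li else if (right_ok) ri - imax else NA
    fwhm <- if (is.na(short)) settings$peak_width_limits[1] else 2 * short * fres
    sd_guess <- fwhm / (2 * sqrt(2 * log(2)))
    lim <- effective_width_limits(cf, settings)
    sd_guess <- min(max(sd_guess, lim[1]), lim[2])
    guesses <- rbind(guesses, c(cf, h, sd_guess))
    work <- work - sd_guess_gauss(freqs, cf, h, sd_guess)
  }
  guesses
}

sd_guess_gauss <- function(freqs, cf, h, s) h * exp(-(freqs - cf)^2 / (2 * s^2))

# Drop peaks whose center is within one SD of the fit-range edge, then drop
# the smaller of any pair of strongly overlapping peaks.
prune_peaks <- function(guesses, fit_range) {
  if (is.null(guesses)) return(NULL)
  keep <- guesses[, 1] - guesses[, 3] > fit_range[1] &
          guesses[, 1] + guesses[, 3] < fit_range[2]
  guesses <- guesses[keep, , drop = FALSE]
  if (nrow(guesses) < 2) return(if (nrow(guesses)) guesses else NULL)
  ord <- order(guesses[, 1])
  guesses <- guesses[ord, , drop = FALSE]
  drop <- rep(FALSE, nrow(guesses))
  for (i in seq_len(nrow(guesses) - 1)) {
    j <- i + 1
    bound <- 0.75 * (guesses[i, 3] + guesses[j, 3])
    if (guesses[j, 1] - guesses[i, 1] < bound) {
      if (guesses[i, 2] < guesses[j, 2]) drop[i] <- TRUE else drop[j] <- TRUE
    }
  }
  out <- guesses[!drop, , drop = FALSE]
  if (nrow(out)) out else NULL
}

# Joint bounded least-squares refinement of all Gaussians on the flattened
# spectrum. Center bounded within 1.5 guess-SD of the guess, height
# non-negative, SD within the effective limits.
refine_peaks <- function(freqs, flat, guesses, settings) {
  if (is.null(guesses)) return(list(params = NULL, converged = TRUE))
  n <- nrow(guesses)
  par0 <- as.vector(t(guesses))
  lower <- upper <- numeric(3 * n)
  for (i in seq_len(n)) {
    lim <- effective_width_limits(guesses[i, 1], settings)
    cfb <- 1.5 * guesses[i, 3]
    lower[(3 * i - 2):(3 * i)] <- c(max(guesses[i, 1] - cfb, settings$fit_range[1]),
                                    0, lim[1])
    upper[(3 * i - 2):(3 * i)] <- c(min(guesses[i, 1] + cfb, settings$fit_range[2]),
                                    Inf, lim[2])
  }
  par0 <- pmin(pmax(par0, lower), upper)
  resid_fun <- function(p) {
    m <- matrix(p, ncol = 3, byrow = TRUE)
    flat - gauss_model(freqs, m)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(params = matrix(par0, ncol = 3, byrow = TRUE), converged = FALSE))
  }
  list(params = matrix(fit$par, ncol = 3, byrow = TRUE),
       converged = fit$info %in% 1:4)
}

#' Fit the aperiodic + periodic spectral model to a power spectrum
#'
#' Models `log10 P(f) = offset - alpha * log10(f) + sum of Gaussians` over
#' the fit range. The procedure is: (1) robust initial aperiodic fit;
#' (2) iterative peak extraction on the flattened spectrum (tallest point,
#' half-height width guess, subtract) until `max_n_peaks` or no point
#' exceeds `peak_threshold` SD of the residual and `min_peak_height`;
#' (3) joint bounded refinement of all Gaussians; (4) aperiodic refit on the
#' peak-removed spectrum. Goodness of fit (R-squared and mean absolute
#' error) is computed between model and data in log10-power.
#'
#' @param psd A `site_psd`, or a numeric power vector (then `freqs` must be
#'   given).
#' @param settings A [fit_settings()].
#' @param freqs Frequency grid when `psd` is a bare vector.
#' @return An `aperiodic_fit`: list with `offset`, `exponent`, `peaks`
#'   (data.frame center/height/bandwidth), `r_squared`, `mae`, `converged`,
#'   plus the fitted `freqs`, `log_power` and `model` vectors.
#' @export
fit_spectrum <- function(psd, settings = fit_settings(), freqs = NULL) {
  if (inherits(psd, "site_psd")) {
    freqs <- psd$freqs
    power <- psd$power
  } else {
    power <- as.numeric(psd)
    if (is.null(freqs)) stop("freqs required when psd is a bare vector")
  }
  sel <- freqs >= settings$fit_range[1] & freqs <= settings$fit_range[2]
  f <- freqs[sel]
  p <- power[sel]
  if (length(f) < 5) stop("fewer than 5 bins in the fit range")
  if (any(p <= 0)) stop("non-positive power in the fit range; cannot take log")
  logf <- log10(f)
  logp <- log10(p)

  ap <- robust_ap_fit(logf, logp)
  flat <- logp - (ap[1] - ap[2] * logf)
  guesses <- guess_peaks(f, flat, settings)
  guesses <- prune_peaks(guesses, settings$fit_range)
  ref <- refine_peaks(f, flat, guesses, settings)
  gfit <- gauss_model(f, ref$params)

  ap_final <- simple_ap_fit(logf, logp - gfit)
  model <- ap_final[1] - ap_final[2] * logf + gfit

  r2 <- if (stats::var(logp) > 0) stats::cor(logp, model)^2 else NA_real_
  mae <- mean(abs(logp - model))

  peaks <- if (is.null(ref$params) || nrow(ref$params) == 0) {
    data.frame(center = numeric(0), height = numeric(0), bandwidth = numeric(0))
  } else {
    ord <- order(ref$params[, 1])
    data.frame(center = ref$params[ord, 1], height = ref$params[ord, 2],
               bandwidth = 2 * ref$params[ord, 3])
  }
  structure(list(offset = unname(ap_final[1]), exponent = unname(ap_final[2]),
                 peaks = peaks, r_squared = r2, mae = mae,
                 converged = ref$converged, settings = settings,
                 freqs = f, log_power = logp, model = model),
            class = "aperiodic_fit")
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat("<aperiodic_fit> offset:", round(x$offset, 3),
      " exponent:", round(x$exponent, 3),
      " peaks:", nrow(x$peaks),
      " R2:", round(x$r_squared, 4), " MAE:", round(x$mae, 4), "\n")
  if (nrow(x$peaks)) print(round(x$peaks, 3))
  invisible(x)
}

#' Evaluate the fitted spectral model on a frequency grid
#'
#' @param fit An `aperiodic_fit`.
#' @param freqs Frequency grid (Hz).
#' @return log10-power of the model.
#' @export
model_spectrum <- function(fit, freqs) {
  g <- if (nrow(fit$peaks)) {
    gauss_model(freqs, cbind(fit$peaks$center, fit$peaks$height,
                             fit$peaks$bandwidth / 2))
  } else numeric(length(freqs))
  fit$offset - fit$exponent * log10(freqs) + g
}

#' Goodness-of-fit surface over simulated test spectra
#'
#' Fits every simulated spectrum and summarizes R-squared and MAE per
#' (exponent, noise, peaks) cell. R-squared values are averaged on the
#' inverse-hyperbolic-tangent scale and back-transformed with tanh; values
#' of exactly 1 are clipped to `1 - 1e-12` before the transform. Undefined
#' R-squared (zero-variance spectra) is dropped from the average.
#'
#' @param sim Output of [simulate_test_spectra()].
#' @param settings A [fit_settings()].
#' @return data.frame with one row per cell: exponent, target_mae,
#'   has_peaks, r2_mean, r2_sd, mae_mean, mae_sd, exponent_mean, n.
#' @export
goodness_surface <- function(sim, settings = fit_settings()) {
  rows <- lapply(sim$cells, function(cell) {
    n <- nrow(cell$log_power)
    r2 <- mae <- expo <- numeric(n)
    for (r in seq_len(n)) {
      fit <- fit_spectrum(10^cell$log_power[r, ], settings, freqs = sim$freqs)
      r2[r] <- fit$r_squared
      mae[r] <- fit$mae
      expo[r] <- fit$exponent
    }
    z <- atanh(pmin(r2[!is.na(r2)], 1 - 1e-12))
    data.frame(exponent = cell$exponent, target_mae = cell$target_mae,
               has_peaks = !is.null(cell$peaks),
               r2_mean = if (length(z)) tanh(mean(z)) else NA_real_,
               r2_sd = if (length(z) > 1) tanh(stats::sd(z)) else NA_real_,
               mae_mean = mean(mae), mae_sd = stats::sd(mae),
               exponent_mean = mean(expo), n = n)
  })
  do.call(rbind, rows)
}
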