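#' Configuration for the synthetic study generator
#'
#' Defaults emulate the study's statistical structure: LFP exponents drawn
#' from N(2.20, 0.40) and SPK exponents from N(0.11, 0.22) (per
#' trajectory), LFP beta center frequencies HiBeta-centered and SPK betaCFs
#' LoBeta-centered (downshifted), ten 400-um pre-STN sites followed by
#' 100-um STN steps, 4-s sites, and clinical responses generated from a
#' known zeroth-order linear model over one predictor family.
#'
#' @param n_patients Number of patients.
#' @param n_trajectories Trajectories per patient.
#' @param fs Sampling rate in Hz.
#' @param duration_s Site duration in seconds.
#' @param subregion_lengths Named mm lengths `c(pre=, motor=, nonmotor=)`;
#'   each must be >= 1 mm (trajectory inclusion criteria).
#' @param pre_step_mm,stn_step_mm Electrode step sizes (mm).
#' @param lfp_exponent,spk_exponent `c(mean, sd)` of the aperiodic exponent
#'   draws; LFP must exceed SPK in expectation.
#' @param lfp_offset,spk_offset `c(mean, sd)` of log10-power offsets.
#' @param lfp_beta_cf,spk_beta_cf `c(mean, sd)` of betaCF draws (Hz).
#' @param lfp_beta_cf_range,spk_beta_cf_range Truncation ranges (Hz).
#' @param lfp_beta_amp,spk_beta_amp Beta sine amplitude as multiple of the
#'   noise SD; SPK beta exists only in the motor subregion.
#' @param clinical_family Predictor family driving the clinical responses.
#' @param clinical_coefficients Length-4 ground-truth coefficient vector.
#' @param noise_sd Response noise SD (z-scale).
#' @return A `study_config` list.
#' @export
study_config <- function(n_patients = 30, n_trajectories = 2, fs = 4096,
                         duration_s = 4,
                         subregion_lengths = c(pre = 4, motor = 3, nonmotor = 3),
                         pre_step_mm = 0.4, stn_step_mm = 0.1,
                         lfp_exponent = c(2.20, 0.40),
                         spk_exponent = c(0.11, 0.22),
                         lfp_offset = c(1.5, 0.3),
                         spk_offset = c(-1.0, 0.3),
                         lfp_beta_cf = c(26, 3),
                         spk_beta_cf = c(17, 2),
                         lfp_beta_cf_range = c(14, 32),
                         spk_beta_cf_range = c(13.5, 20),
                         lfp_beta_amp = 0.5, spk_beta_amp = 0.5,
                         clinical_family = "ApF",
                         clinical_coefficients = c(0.5, -0.3, 0.4, 0.2),
                         noise_sd = 0.3) {
  stopifnot(n_patients >= 1, n_trajectories >= 1,
            all(names(subregion_lengths) == c("pre", "motor", "nonmotor")),
            length(clinical_coefficients) == 4)
  if (any(subregion_lengths < 1)) {
    stop("each subregion must be at least 1 mm (inclusion criteria)")
  }
  if (lfp_exponent[1] <= spk_exponent[1]) {
    stop("LFP exponent mean must exceed SPK exponent mean")
  }
  structure(as.list(environment()), class = "study_config")
}

#' Colored (power-law) noise via spectral shaping
#'
#' Gaussian white noise whose Fourier magnitudes are scaled by
#' `f^(-alpha/2)`, giving a PSD proportional to `1/f^alpha`; the DC bin is
#' zeroed. Components below `low_cut` Hz can be zeroed to emulate a
#' band-limited acquisition chain with an exact in-band power law (steep
#' spectra otherwise leak sub-band power across the analysis window's
#' sidelobes). The result is rescaled to unit SD.
#'
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @param alpha Target spectral exponent.
#' @param low_cut Zero all components below this frequency (Hz; 0 = none).
#' @return Numeric vector of length `n` with SD 1.
#' @export
colored_noise <- function(n, fs, alpha, low_cut = 0) {
  X <- stats::fft(stats::rnorm(n))
  f <- seq(0, n - 1) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]
  scale <- c(0, f[-1]^(-alpha / 2))
  if (low_cut > 0) scale[f < low_cut] <- 0
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

rnorm_trunc <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < range[1] | x > range[2])) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

site_layout <- function(cfg) {
  n_pre <- max(10L, ceiling(cfg$subregion_lengths[["pre"]] / cfg$pre_step_mm))
  pre_depths <- -rev(seq_len(n_pre)) * cfg$pre_step_mm
  stn_len <- cfg$subregion_lengths[["motor"]] + cfg$subregion_lengths[["nonmotor"]]
  stn_depths <- seq(cfg$stn_step_mm, stn_len, by = cfg$stn_step_mm)
  depths <- c(pre_depths, stn_depths)
  subregion <- ifelse(depths <= 0, "pre",
                      ifelse(depths <= cfg$subregion_lengths[["motor"]],
                             "motor", "nonmotor"))
  list(depths_mm = depths, subregion = subregion, entry_mm = 0, exit_mm = stn_len)
}

#' Generate a synthetic study dataset with known ground truth
#'
#' Per trajectory, draws an LFP exponent, SPK exponent, offsets, and stream
#' beta center frequencies; per site, synthesizes a 4-s LFP (colored noise
#' at the trajectory exponent plus a beta sine at the LFP betaCF, all
#' subregions) and SPK (near-white noise plus a beta sine at the downshifted
#' SPK betaCF, motor subregion only). Clinical responses are linear in the
#' z-normalized members of `clinical_family` with the configured
#' coefficients plus Gaussian noise. Every drawn parameter is recorded in
#' the ground-truth sidecar.
#'
#' @param cfg A [study_config()].
#' @param signals Generate the per-site signal matrices (default TRUE).
#'   `FALSE` draws the trajectory parameters and clinical table only, for
#'   statistical experiments that do not touch the signal path.
#' @return List of class `synthetic_study`: `config`, `trajectories` (each
#'   with depths, subregion labels, lfp/spk signal matrices), `clinical`
#'   (data.frame), `ground_truth`.
#' @export
simulate_study <- function(cfg = study_config(), signals = TRUE) {
  stopifnot(inherits(cfg, "study_config"))
  layout <- site_layout(cfg)
  n_samp <- round(cfg$duration_s * cfg$fs)
  t <- (seq_len(n_samp) - 1) / cfg$fs
  trajectories <- list()
  truth_rows <- list()
  for (p in seq_len(cfg$n_patients)) {
    for (tr in seq_len(cfg$n_trajectories)) {
      a_l <- stats::rnorm(1, cfg$lfp_exponent[1], cfg$lfp_exponent[2])
      a_s <- stats::rnorm(1, cfg$spk_exponent[1], cfg$spk_exponent[2])
      o_l <- stats::rnorm(1, cfg$lfp_offset[1], cfg$lfp_offset[2])
      o_s <- stats::rnorm(1, cfg$spk_offset[1], cfg$spk_offset[2])
      cf_l <- rnorm_trunc(1, cfg$lfp_beta_cf[1], cfg$lfp_beta_cf[2],
                          cfg$lfp_beta_cf_range)
      cf_s <- rnorm_trunc(1, cfg$spk_beta_cf[1], cfg$spk_beta_cf[2],
                          cfg$spk_beta_cf_range)
      ns <- length(layout$depths_mm)
      if (signals) {
        lfp <- matrix(NA_real_, n_samp, ns)
        spk <- matrix(NA_real_, n_samp, ns)
        g_l <- 10^(o_l / 2)
        g_s <- 10^(o_s / 2)
        beta_l <- cfg$lfp_beta_amp * sin(2 * pi * cf_l * t)
        beta_s <- cfg$spk_beta_amp * sin(2 * pi * cf_s * t)
        # The container carries pre-split streams: the LFP channel is
        # band-limited (it has passed the 3-200 Hz acquisition band-pass),
        # so the synthetic LFP carries no sub-band power, but keeps an
        # exact power law inside the analysis band.
        for (k in seq_len(ns)) {
          lfp[, k] <- g_l * (colored_noise(n_samp, cfg$fs, a_l, low_cut = 2.5) +
                               beta_l)
          base <- colored_noise(n_samp, cfg$fs, a_s)
          if (layout$subregion[k] == "motor") base <- base + beta_s
          spk[, k] <- g_s * base
        }
        trajectories[[length(trajectories) + 1L]] <-
          list(patient = p, trajectory = tr, fs = cfg$fs,
               depths_mm = layout$depths_mm, subregion = layout$subregion,
               entry_mm = layout$entry_mm, exit_mm = layout$exit_mm,
               lfp = lfp, spk = spk)
      }
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(patient = p, trajectory = tr, lfp_exponent = a_l,
                   spk_exponent = a_s, lfp_offset = o_l, spk_offset = o_s,
                   lfp_beta_cf = cf_l, spk_beta_cf = cf_s,
                   lfp_beta_amp = cfg$lfp_beta_amp,
                   spk_beta_amp = cfg$spk_beta_amp)
    }
  }
  truth <- do.call(rbind, truth_rows)
  clinical <- make_clinical_table(cfg, truth)
  structure(list(config = cfg, trajectories = trajectories,
                 clinical = clinical$table,
                 ground_truth = list(trajectories = truth,
                                     clinical_family = cfg$clinical_family,
                                     clinical_coefficients = cfg$clinical_coefficients,
                                     noise_sd = cfg$noise_sd,
                                     response_noise = clinical$noise)),
            class = "synthetic_study")
}

# Patient-level predictor table + responses from the ground-truth linear
# model. Neural predictors are patient means of the drawn trajectory
# parameters; demographics are drawn from realistic cohort distributions.
make_clinical_table <- function(cfg, truth) {
  agg <- stats::aggregate(truth[, c("lfp_exponent", "spk_exponent",
                                    "lfp_offset", "spk_offset",
                                    "lfp_beta_cf", "spk_beta_cf",
                                    "lfp_beta_amp", "spk_beta_amp")],
                          by = list(patient = truth$patient), FUN = mean)
  n <- nrow(agg)
  tab <- data.frame(patient = agg$patient,
                    LD = stats::rnorm(n, 600, 150),
                    Ag = stats::rnorm(n, 60, 8),
                    DD = stats::rnorm(n, 10, 3),
                    Gd = stats::rbinom(n, 1, 0.5),
                    LCF = agg$lfp_beta_cf, SCF = agg$spk_beta_cf,
                    LP = agg$lfp_beta_amp + stats::rnorm(n, 0, 0.05),
                    SP = agg$spk_beta_amp + stats::rnorm(n, 0, 0.05),
                    LO = agg$lfp_offset, SO = agg$spk_offset,
                    LE = agg$lfp_exponent, SE = agg$spk_exponent)
  tab$LSCF <- tab$LCF - tab$SCF
  tab$LSP <- tab$LP - tab$SP
  tab$LSO <- tab$LO - tab$SO
  tab$LSE <- tab$LE - tab$SE
  members <- family_members(cfg$clinical_family)
  X <- scale(as.matrix(tab[, members]))
  lin <- as.numeric(X %*% cfg$clinical_coefficients)
  noise <- list()
  for (resp in c("DRT_Off", "DRT_Diff", "DRT_Per", "DBS_Diff", "DBS_Per",
                 "DBS_Eva")) {
    eps <- stats::rnorm(n, 0, cfg$noise_sd)
    y <- lin + eps
    if (resp == "DBS_Eva") y <- pmin(pmax(round(y), -2), 2)
    tab[[resp]] <- y
    noise[[resp]] <- eps
  }
  tab$phenotype <- sample(c("akinetic_rigid", "tremor"), n, replace = TRUE)
  list(table = tab, noise = noise)
}

# CSV writer preserving doubles exactly: 17 significant digits always
# round-trip through strtod.
fwrite_precise <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  data.table::fwrite(df, path, quote = FALSE)
}

#' Write a synthetic study to a plain-text directory container
#'
#' Layout: `manifest.csv` (one row per trajectory), `clinical.csv`,
#' `ground_truth.json`, and per-trajectory signal matrices under `signals/`
#' (`p<patient>_t<trajectory>_<stream>.csv`, one column per site). Doubles
#' are written with full round-trip precision.
#'
#' @param study A `synthetic_study`.
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(file.path(dir, "signals"), recursive = TRUE, showWarnings = FALSE)
  man <- do.call(rbind, lapply(study$trajectories, function(tj) {
    data.frame(patient = tj$patient, trajectory = tj$trajectory, fs = tj$fs,
               n_sites = length(tj$depths_mm), entry_mm = tj$entry_mm,
               exit_mm = tj$exit_mm,
               motor_end_mm = max(tj$depths_mm[tj$subregion == "motor"]))
  }))
  fwrite_precise(man, file.path(dir, "manifest.csv"))
  fwrite_precise(study$clinical, file.path(dir, "clinical.csv"))
  gt <- study$ground_truth
  fwrite_precise(gt$trajectories, file.path(dir, "ground_truth_trajectories.csv"))
  jsonlite::write_json(
    list(clinical_family = gt$clinical_family,
         clinical_coefficients = sprintf("%.17g", gt$clinical_coefficients),
         noise_sd = sprintf("%.17g", gt$noise_sd)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  for (tj in study$trajectories) {
    stem <- sprintf("p%d_t%d", tj$patient, tj$trajectory)
    meta <- data.frame(depth_mm = tj$depths_mm, subregion = tj$subregion)
    fwrite_precise(meta, file.path(dir, "signals", paste0(stem, "_sites.csv")))
    fwrite_precise(as.data.frame(tj$lfp),
                   file.path(dir, "signals", paste0(stem, "_lfp.csv")))
    fwrite_precise(as.data.frame(tj$spk),
                   file.path(dir, "signals", paste0(stem, "_spk.csv")))
  }
  # config fields needed to rebuild the object
  cfgl <- unclass(study$config)
  jsonlite::write_json(cfgl, file.path(dir, "config.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a synthetic study back from its directory container
#'
#' @param dir Directory written by [write_study()].
#' @return A `synthetic_study`.
#' @export
read_study <- function(dir) {
  man <- data.table::fread(file.path(dir, "manifest.csv"), data.table = FALSE)
  clinical <- data.table::fread(file.path(dir, "clinical.csv"), data.table = FALSE)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  gt_traj <- data.table::fread(file.path(dir, "ground_truth_trajectories.csv"),
                               data.table = FALSE)
  cfgl <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfgl$subregion_lengths <- unlist(cfgl$subregion_lengths)
  cfg <- do.call(study_config, cfgl)
  trajectories <- lapply(seq_len(nrow(man)), function(i) {
    stem <- sprintf("p%d_t%d", man$patient[i], man$trajectory[i])
    meta <- data.table::fread(file.path(dir, "signals", paste0(stem, "_sites.csv")),
                              data.table = FALSE)
    lfp <- as.matrix(data.table::fread(
      file.path(dir, "signals", paste0(stem, "_lfp.csv")), data.table = FALSE))
    spk <- as.matrix(data.table::fread(
      file.path(dir, "signals", paste0(stem, "_spk.csv")), data.table = FALSE))
    dimnames(lfp) <- dimnames(spk) <- NULL
    list(patient = man$patient[i], trajectory = man$trajectory[i],
         fs = man$fs[i], depths_mm = meta$depth_mm, subregion = meta$subregion,
         entry_mm = man$entry_mm[i], exit_mm = man$exit_mm[i],
         lfp = lfp, spk = spk)
  })
  structure(list(config = cfg, trajectories = trajectories,
                 clinical = clinical,
                 ground_truth = list(
                   trajectories = gt_traj,
                   clinical_family = gt$clinical_family,
                   clinical_coefficients = as.numeric(gt$clinical_coefficients),
                   noise_sd = as.numeric(gt$noise_sd))),
            class = "synthetic_study")
}
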