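test_that("the study container round-trips losslessly through the writer/reader", {
  set.seed(31)
  cfg <- study_config(n_patients = 1, n_trajectories = 2, fs = 512,
                      duration_s = 4,
                      subregion_lengths = c(pre = 4, motor = 1.2, nonmotor = 1.2))
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  st2 <- read_study(dir)
  expect_identical(st$trajectories[[1]]$lfp, st2$trajectories[[1]]$lfp)
  expect_identical(st$trajectories[[2]]$spk, st2$trajectories[[2]]$spk)
  expect_identical(st$trajectories[[1]]$subregion, st2$trajectories[[1]]$subregion)
  expect_true(all.equal(st$clinical, st2$clinical, tolerance = 0))
  expect_true(all.equal(st$ground_truth$trajectories,
                        st2$ground_truth$trajectories, tolerance = 0))
  expect_identical(st$ground_truth$clinical_coefficients,
                   st2$ground_truth$clinical_coefficients)
})

test_that("site layout honors the trajectory depth structure", {
  set.seed(32)
  st <- simulate_study(study_config(n_patients = 1, n_trajectories = 1,
                                    fs = 256, duration_s = 4), signals = TRUE)
  tj <- st$trajectories[[1]]
  pre <- tj$depths_mm[tj$subregion == "pre"]
  stn <- tj$depths_mm[tj$subregion != "pre"]
  expect_gte(length(pre), 10)
  expect_equal(unique(round(diff(pre), 10)), 0.4)
  expect_equal(unique(round(diff(stn), 10)), 0.1)
  expect_equal(tj$entry_mm, 0)
  expect_true(all(pre < 0))
  # each site lasts duration_s
  expect_equal(nrow(tj$lfp), 4 * 256)
})

test_that("forced betaCFs give a downshift fraction of exactly one", {
  set.seed(33)
  cfg <- study_config(n_patients = 3, n_trajectories = 2,
                      lfp_beta_cf = c(26, 0), lfp_beta_cf_range = c(26, 26),
                      spk_beta_cf = c(17, 0), spk_beta_cf_range = c(17, 17))
  st <- simulate_study(cfg, signals = FALSE)
  tr <- st$ground_truth$trajectories
  d <- summarize_downshift(tr$lfp_beta_cf, tr$spk_beta_cf)
  expect_equal(d$fraction_down, 1)
})

test_that("noiseless clinical responses recover the coefficients exactly", {
  set.seed(34)
  cfg <- study_config(n_patients = 25, noise_sd = 0)
  st <- simulate_study(cfg, signals = FALSE)
  fit <- suppressWarnings(fit_family(st$clinical, "ApF", "DRT_Off", order = "zeroth"))
  est <- fit$coefficients$estimate[match(family_members("ApF"),
                                         fit$coefficients$term)]
  truth <- cfg$clinical_coefficients
  # response is z-normalized, so recovered coefficients are the truth
  # divided by the SD of the noiseless linear predictor
  s <- sd(as.numeric(scale(as.matrix(st$clinical[, family_members("ApF")])) %*% truth))
  expect_equal(est * s, truth, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("generator calibration: mean drawn LFP exponent near 2.20", {
  set.seed(35)
  st <- simulate_study(study_config(n_patients = 30), signals = FALSE)
  tr <- st$ground_truth$trajectories
  se <- sd(tr$lfp_exponent) / sqrt(nrow(tr))
  expect_lt(abs(mean(tr$lfp_exponent) - 2.20), 2 * se + 1e-9)
  expect_gt(mean(tr$lfp_exponent), mean(tr$spk_exponent))
})

test_that("the clinical table satisfies derived-column consistency", {
  set.seed(36)
  st <- simulate_study(study_config(n_patients = 10), signals = FALSE)
  expect_silent(check_clinical_table(st$clinical))
  bad <- st$clinical
  bad$LSE[1] <- bad$LSE[1] + 1
  expect_error(check_clinical_table(bad), "LSE")
})
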