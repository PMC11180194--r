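test_that("edge trimming retains exactly half the generated samples", {
  set.seed(1)
  out <- simulate_brown_beta(sim_signal_config())
  expect_length(out$brown, 4096)
  expect_length(out$rectified_beta_modulated, 4096)
  out2 <- simulate_brown_beta(sim_signal_config(n_samples = 4096))
  expect_length(out2$brown, 2048)
})

test_that("zero beta amplitude leaves the Brown noise untouched", {
  set.seed(2)
  out <- simulate_brown_beta(sim_signal_config(beta_amp_factor = 0))
  expect_identical(out$beta_modulated, out$brown)
})

test_that("simulated Brown noise has a log-log PSD slope near -2", {
  set.seed(3)
  cfg <- sim_signal_config()
  avg <- average_sim_psd(function() simulate_brown_beta(cfg), "brown",
                         n_rep = 300, fs = cfg$fs, fmax = 200)
  sel <- avg$freqs >= 3 & avg$freqs <= 70
  slope <- stats::coef(stats::lm(log10(avg$power[sel]) ~ log10(avg$freqs[sel])))[[2]]
  expect_equal(slope, -2, tolerance = 0.05)
})

test_that("spike counts are Poisson-mean-consistent over many beta peaks", {
  set.seed(4)
  cfg <- sim_signal_config()
  total_spikes <- 0
  total_regions <- 0
  for (i in 1:90) {
    s <- simulate_spiking(cfg)
    total_spikes <- total_spikes + s$n_spikes
    total_regions <- total_regions + s$n_regions
  }
  expect_gt(total_regions, 1000)
  expect_equal(total_spikes / total_regions, cfg$spike_rate_mean,
               tolerance = 0.05)
})

test_that("zero spike rate leaves no beta peak in the rectified spiking band", {
  set.seed(5)
  cfg0 <- sim_signal_config(spike_rate_mean = 0)
  avg <- average_sim_psd(function() simulate_spiking(cfg0), "rectified_spk",
                         n_rep = 60, fs = cfg0$fs, fmax = 100)
  lp <- log10(avg$power)
  contrast <- lp[avg$freqs == 20] -
    mean(lp[avg$freqs %in% c(16, 17, 23, 24)])
  expect_lt(abs(contrast), 0.1)
})

test_that("generators are bit-reproducible given a seed", {
  set.seed(10)
  a <- simulate_spiking(sim_signal_config())
  set.seed(10)
  b <- simulate_spiking(sim_signal_config())
  expect_identical(a, b)
  set.seed(11)
  s1 <- simulate_test_spectra(spectrum_sim_config(n_repeats = 2,
                                                  noise_mae_grid = 0.05))
  set.seed(11)
  s2 <- simulate_test_spectra(spectrum_sim_config(n_repeats = 2,
                                                  noise_mae_grid = 0.05))
  expect_identical(s1, s2)
})

test_that("test spectra have offset = exponent and exact realized noise MAE", {
  set.seed(6)
  cfg <- spectrum_sim_config(exponent_grid = c(0, 1.5),
                             noise_mae_grid = c(0, 0.08), n_repeats = 3)
  sim <- simulate_test_spectra(cfg)
  freqs <- sim$freqs
  for (cell in sim$cells) {
    base <- cell$offset - cell$exponent * log10(freqs)
    resid <- sweep(cell$log_power, 2, base)
    if (cell$target_mae == 0) {
      expect_equal(max(abs(resid)), 0)
    } else {
      expect_equal(rowMeans(abs(resid)), rep(cell$target_mae, 3),
                   tolerance = 1e-12)
    }
    expect_identical(cell$offset, cell$exponent)
  }
})

test_that("a flat noiseless spectrum is degenerate: MAE 0, R-squared undefined", {
  set.seed(7)
  sim <- simulate_test_spectra(spectrum_sim_config(
    exponent_grid = 0, noise_mae_grid = 0, n_repeats = 2))
  g <- goodness_surface(sim)
  expect_equal(g$mae_mean, 0, tolerance = 1e-10)
  expect_true(is.na(g$r2_mean))
})

test_that("empty spike trains are flagged in metadata, not errors", {
  # threshold above the membrane maximum cannot occur with the default
  # percentile; force the degenerate path with zero spikes instead
  set.seed(8)
  s <- simulate_spiking(sim_signal_config(spike_rate_mean = 0))
  expect_true(s$empty_spike_train)
  expect_equal(sum(s$spike_train), 0)
})
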