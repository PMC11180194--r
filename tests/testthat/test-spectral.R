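test_that("2-s Hamming windows give an exact 0.5 Hz grid", {
  set.seed(1)
  for (fs in c(1024, 4096)) {
    psd <- welch_psd(rnorm(4 * fs), fs)
    expect_equal(unique(round(diff(psd$freqs), 10)), 0.5)
  }
})

test_that("short sites are marked excluded rather than erring", {
  psd <- welch_psd(rnorm(1000), fs = 1000, window_s = 2)
  expect_true(psd$excluded)
  expect_error(welch_psd(rnorm(4000), fs = 300, fmax = 200), "fmax")
})

test_that("white noise gives a flat spectrum within estimator tolerance", {
  set.seed(2)
  fs <- 1024
  acc <- 0
  nrep <- 50
  for (i in seq_len(nrep)) acc <- acc + welch_psd(rnorm(4 * fs), fs)$power
  p <- acc / nrep
  psd1 <- welch_psd(rnorm(4 * fs), fs)
  sel <- psd1$freqs >= 3 & psd1$freqs <= 200
  # unit-variance white noise has two-sided density 1/fs, one-sided 2/fs
  expect_equal(mean(p[sel]), 2 / fs, tolerance = 0.05)
  expect_lt(stats::sd(p[sel]) / mean(p[sel]), 3 / sqrt(3 * nrep))
})

test_that("a pure sine lands in its own bin with Parseval-consistent power", {
  fs <- 1024
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  for (a in c(1, 2.5)) {
    psd <- welch_psd(a * sin(2 * pi * 20 * t), fs)
    expect_equal(psd$freqs[which.max(psd$power)], 20)
    total <- sum(psd$power) * 0.5  # bin width
    expect_equal(total, a^2 / 2, tolerance = 0.05)
  }
})

test_that("line-noise repair replaces notch bands and is idempotent", {
  f <- seq(0.5, 200, 0.5)
  p <- rep(1, length(f))
  p[f == 50] <- 100
  psd <- site_psd(f, p)
  rep1 <- repair_line_noise(psd)
  expect_equal(rep1$power[f == 50], 1)
  # untouched away from harmonics
  expect_equal(rep1$power[f == 30], 1)
  expect_identical(repair_line_noise(rep1)$power, rep1$power)
  # flat spectrum unchanged everywhere
  flat <- site_psd(f, rep(2, length(f)))
  expect_equal(repair_line_noise(flat)$power, rep(2, length(f)))
})

test_that("all mains harmonics up to the grid top are repaired", {
  f <- seq(0.5, 200, 0.5)
  p <- rep(1, length(f))
  spikes <- c(50, 100, 150, 200)
  p[f %in% spikes] <- 50
  fixed <- repair_line_noise(site_psd(f, p))
  expect_equal(fixed$power[f %in% spikes], rep(1, 4))
})

test_that("frequency normalization yields unit total power and scale invariance", {
  f <- seq(0.5, 200, 0.5)
  set.seed(3)
  p <- rlnorm(length(f))
  n1 <- normalize_by_frequency(site_psd(f, p))
  sel <- f >= 3 & f <= 200
  expect_equal(sum(n1$power[sel]), 1)
  n2 <- normalize_by_frequency(site_psd(f, 37 * p))
  expect_equal(n1$power, n2$power)
  expect_identical(n1$norm_state, "freq_norm")
  toy <- normalize_by_frequency(site_psd(c(3, 4), c(3, 1)), total_range = c(3, 4))
  expect_equal(toy$power, c(0.75, 0.25))
})

test_that("distance normalization z-scores against the 10 baseline sites", {
  f <- seq(3, 70, 0.5)
  set.seed(4)
  base <- lapply(1:10, function(i) site_psd(f, 2 + rnorm(length(f)),
                                            norm_state = "freq_norm"))
  site <- site_psd(f, 5 + numeric(length(f)), norm_state = "freq_norm")
  zs <- normalize_by_distance(c(base, list(site)))
  mat <- do.call(rbind, lapply(base, function(p) p$power))
  expect_equal(zs[[11]]$power, (5 - colMeans(mat)) / apply(mat, 2, sd))
  # baseline mean z is 0 per bin by construction
  zmat <- do.call(rbind, lapply(zs[1:10], function(p) p$power))
  expect_equal(colMeans(zmat), numeric(length(f)))
})

test_that("identical signals give unit coherence, shared sines a coherence peak", {
  set.seed(5)
  fs <- 1024
  x <- rnorm(4 * fs)
  co <- mscoherence(x, x, fs)
  expect_equal(co$coherence, rep(1, nrow(co)), tolerance = 1e-9)
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  shared <- sin(2 * pi * 20 * t)
  co2 <- mscoherence(shared + rnorm(length(t)), shared + rnorm(length(t)), fs)
  expect_equal(co2$freq[which.max(co2$coherence)], 20)
  # invariance to independent rescaling
  a <- rnorm(4 * fs); b <- rnorm(4 * fs)
  expect_equal(mscoherence(a, b, fs)$coherence,
               mscoherence(3 * a, 0.2 * b, fs)$coherence)
})

test_that("coherence bias under independence matches the few-segment estimator", {
  set.seed(6)
  fs <- 1024
  m <- replicate(100, mean(mscoherence(rnorm(4 * fs), rnorm(4 * fs), fs)$coherence))
  # 4-s records with 2-s windows at 50% overlap give 3 segments: bias ~ 1/3,
  # slightly above due to segment overlap (Monte-Carlo value ~0.348)
  expect_gt(mean(m), 0.32)
  expect_lt(mean(m), 0.38)
})

test_that("normalized distance maps entry to 0, exit to 1, pre-STN negative", {
  f <- seq(3, 70, 0.5)
  psds <- lapply(1:4, function(i) site_psd(f, rep(i, length(f))))
  depths <- c(-1, 0, 2.5, 5)
  sg <- build_spectrogram(psds, depths, entry_mm = 0, exit_mm = 5)
  expect_equal(sg$nd, c(-0.2, 0, 0.5, 1))
  expect_error(build_spectrogram(psds, depths, entry_mm = 5, exit_mm = 0), "exit")
})
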