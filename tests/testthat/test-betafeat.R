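test_that("the highest local peak in 13-33 Hz defines the beta center frequency", {
  expect_equal(detect_beta_cf(gauss_bump_psd(center = 25))$beta_cf, 25)
  # monotone spectrum: no local maximum in band
  f <- seq(3, 70, 0.5)
  mono <- site_psd(f, 10 - 0.1 * f)
  expect_false(detect_beta_cf(mono)$has_peak)
  # highest of two bumps wins
  two <- site_psd(f, 3 * exp(-(f - 17)^2 / 2) + 2 * exp(-(f - 28)^2 / 2))
  expect_equal(detect_beta_cf(two)$beta_cf, 17)
})

test_that("detect -> align -> detect is idempotent at DeltaF = 0", {
  psd <- gauss_bump_psd(center = 26)
  cf <- detect_beta_cf(psd)$beta_cf
  aligned <- align_to_cf(psd, cf)
  cf2 <- detect_beta_cf(aligned, band = c(-10, 10))$beta_cf
  expect_equal(cf2, 0)
})

test_that("aligned population averages peak at DeltaF = 0", {
  f <- seq(3, 70, 0.5)
  cfs <- c(18, 22, 30)
  aligned <- lapply(cfs, function(c0) {
    psd <- gauss_bump_psd(center = c0, sd = 1.5)
    align_to_cf(psd, detect_beta_cf(psd)$beta_cf)
  })
  # common DeltaF grid: all shifted grids align on 0.5 Hz bins offset by cf
  grid <- seq(-8, 8, 0.5)
  avg <- rowMeans(vapply(aligned, function(p) {
    approx(p$freqs, p$power, xout = grid)$y
  }, numeric(length(grid))))
  expect_equal(grid[which.max(avg)], 0)
})

test_that("half-band width of a Gaussian peak matches the analytic FWHM", {
  sigma <- 2
  bw <- measure_bandwidth(gauss_bump_psd(center = 24, sd = sigma))
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  expect_equal(bw$half_band_width, fwhm, tolerance = 0.5 / fwhm)
  expect_equal(bw$half_left, bw$half_right, tolerance = 0.1)
  expect_equal(bw$half_band_width, bw$half_left + bw$half_right)
  # quarter-height width is wider, three-quarter narrower
  expect_gt(bw$quarter_band_width, bw$half_band_width)
  expect_lt(bw$three_quarter_band_width, bw$half_band_width)
})

test_that("triangular peaks give exact interpolated half-side widths", {
  f <- seq(13, 33, 0.5)
  p <- pmax(0, 3 - abs(f - 23))  # half-width 3 Hz per side at base
  bw <- measure_bandwidth(site_psd(f, p), band = c(13, 33))
  expect_equal(bw$half_left, 1.5)
  expect_equal(bw$half_right, 1.5)
})

test_that("asymmetric peaks yield proportionally asymmetric half-sides", {
  f <- seq(3, 70, 0.5)
  s_l <- 1; s_r <- 3
  p <- ifelse(f <= 22, exp(-(f - 22)^2 / (2 * s_l^2)),
              exp(-(f - 22)^2 / (2 * s_r^2)))
  bw <- measure_bandwidth(site_psd(f, p))
  expect_equal(bw$half_right / bw$half_left, 3, tolerance = 0.15)
})

test_that("bandwidths are invariant to positive rescaling of the NPSD", {
  psd <- gauss_bump_psd(center = 20, sd = 2.5, background = 0.3)
  bw1 <- measure_bandwidth(psd)
  psd$power <- psd$power * 42
  bw2 <- measure_bandwidth(psd)
  expect_equal(bw1$half_band_width, bw2$half_band_width)
  expect_equal(bw1$prominence * 42, bw2$prominence)
})

test_that("downshift fractions and the signed-rank test behave at the extremes", {
  lfp <- c(26, 27, 24, 28, 25)
  d <- summarize_downshift(lfp, lfp - 8)
  expect_equal(d$fraction_down, 1)
  expect_equal(d$fraction_up, 0)
  expect_equal(d$n_pairs, 5)
  expect_lt(d$p_value, 0.1)  # n = 5 floor for the signed-rank test
  same <- summarize_downshift(lfp, lfp)
  expect_equal(same$fraction_equal, 1)
  expect_true(is.na(same$p_value))
  # NA pairs are dropped
  d2 <- summarize_downshift(c(lfp, NA), c(lfp - 8, 20))
  expect_equal(d2$n_pairs, 5)
})

test_that("fractions down/up/equal always sum to one", {
  set.seed(1)
  for (i in 1:20) {
    l <- runif(30, 14, 32)
    s <- l + rnorm(30, -1, 2)
    d <- summarize_downshift(l, s)
    expect_equal(d$fraction_down + d$fraction_up + d$fraction_equal, 1)
  }
})

test_that("population width shrinks after alignment when betaCFs disperse", {
  # narrow single-site peaks (sd 1 Hz) with dispersed centers (sd ~4 Hz):
  # unaligned population average is broad, aligned average stays narrow
  set.seed(2)
  cfs <- pmin(pmax(rnorm(40, 23, 4), 14), 32)
  psds <- lapply(cfs, function(c0) gauss_bump_psd(center = c0, sd = 1))
  pop_unaligned <- site_psd(psds[[1]]$freqs,
                            rowMeans(vapply(psds, function(p) p$power,
                                            numeric(length(psds[[1]]$power)))))
  grid <- seq(-9, 9, 0.5)
  pop_aligned <- site_psd(grid, rowMeans(vapply(psds, function(p) {
    cf <- detect_beta_cf(p)$beta_cf
    approx(p$freqs - cf, p$power, xout = grid)$y
  }, numeric(length(grid)))))
  bw_un <- measure_bandwidth(pop_unaligned)
  bw_al <- measure_bandwidth(pop_aligned, band = c(-5, 5))
  expect_lt(bw_al$half_band_width, bw_un$half_band_width)
  single <- measure_bandwidth(psds[[1]])
  expect_lt(abs(bw_al$half_band_width - single$half_band_width), 1)
})
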