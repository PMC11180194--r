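test_that("family definitions match the study's predictor groups", {
  expect_equal(family_members("DeF"), c("LD", "Ag", "DD", "Gd"))
  expect_equal(family_members("ApF"), c("LO", "SO", "LE", "SE"))
  expect_equal(family_members("PeF"), c("LCF", "SCF", "LP", "SP"))
  expect_equal(family_members("LSF"), c("LSCF", "LSP", "LSO", "LSE"))
  expect_error(family_members("XYZ"), "unknown")
})

make_tab <- function(n, seed = 1) {
  set.seed(seed)
  tab <- data.frame(LO = rnorm(n), SO = rnorm(n), LE = rnorm(n), SE = rnorm(n))
  tab
}

test_that("interaction orders produce the documented term counts", {
  tab <- make_tab(40)
  tab$y <- rnorm(40)
  for (spec in list(c("zeroth", 4), c("first", 6), c("higher", 5))) {
    fit <- fit_family(tab, "ApF", "y", order = spec[1])
    expect_equal(nrow(fit$coefficients), as.numeric(spec[2]) + 1)  # + intercept
  }
  ind <- fit_family(tab, "LO", "y", order = "individual")
  expect_equal(nrow(ind$coefficients), 2)
})

test_that("a noiseless zeroth-order system is solved exactly", {
  tab <- make_tab(30)
  a <- c(0.8, -0.5, 0.3, 0.1)
  X <- scale(as.matrix(tab))
  tab$y <- as.numeric(X %*% a)
  fit <- suppressWarnings(fit_family(tab, "ApF", "y", order = "zeroth"))
  est <- fit$coefficients$estimate[match(c("LO", "SO", "LE", "SE"),
                                         fit$coefficients$term)]
  expect_equal(est * sd(tab$y), a, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$model_p, 1e-12)
})

test_that("standardized fits are invariant to affine rescaling of predictors", {
  tab <- make_tab(35, seed = 2)
  tab$y <- rnorm(35)
  f1 <- fit_family(tab, "ApF", "y", order = "first")
  tab2 <- tab
  tab2$LO <- 100 + 7 * tab2$LO
  tab2$SE <- -3 * tab2$SE + 1
  f2 <- fit_family(tab2, "ApF", "y", order = "first")
  expect_equal(abs(f1$coefficients$estimate), abs(f2$coefficients$estimate),
               tolerance = 1e-10)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
})

test_that("z-normalization is idempotent", {
  set.seed(3)
  x <- rnorm(50, 10, 4)
  z1 <- stnio:::z_norm(x)
  expect_equal(stnio:::z_norm(z1), z1)
})

test_that("AIC selects the generating interaction order", {
  # data generated from the first-order (pairwise product) model must win
  # the AIC comparison against zeroth and higher orders most of the time
  set.seed(4)
  wins <- 0
  nrep <- 100
  for (r in seq_len(nrep)) {
    tab <- make_tab(60, seed = 1000 + r)
    X1 <- stnio:::family_design(tab, c("LO", "SO", "LE", "SE"), "first")
    tab$y <- as.numeric(X1 %*% c(0.9, -0.6, 0.5, 0.4, -0.3, 0.2)) + rnorm(60, 0, 0.7)
    aics <- vapply(c("zeroth", "first", "higher"), function(o) {
      fit_family(tab, "ApF", "y", order = o)$aic
    }, numeric(1))
    if (which.min(aics) == 2) wins <- wins + 1
  }
  expect_gte(wins / nrep, 0.9)
})

test_that("the signal x subregion ANOVA detects the exponent gap instantly", {
  set.seed(5)
  n <- 200
  fits <- expand.grid(stream = c("LFP", "SPK"),
                      subregion = c("pre", "motor", "nonmotor"))
  fits <- fits[rep(seq_len(6), each = n), ]
  fits$exponent <- ifelse(fits$stream == "LFP", rnorm(6 * n, 2.2, 0.4),
                          rnorm(6 * n, 0.11, 0.22))
  res <- anova_aperiodic(fits, "exponent")
  expect_lt(res$p_signal, 1e-10)
  # location invariance
  fits2 <- fits
  fits2$exponent <- fits2$exponent + 100
  res2 <- anova_aperiodic(fits2, "exponent")
  expect_equal(res$p_signal, res2$p_signal, tolerance = 1e-9)
  expect_equal(res$p_interaction, res2$p_interaction, tolerance = 1e-9)
})

test_that("empty cells are rejected with a message", {
  set.seed(8)
  fits <- data.frame(
    stream = rep(c("LFP", "LFP", "LFP", "SPK", "SPK"), each = 10),
    subregion = rep(c("pre", "motor", "nonmotor", "pre", "motor"), each = 10),
    exponent = rnorm(50))
  expect_error(anova_aperiodic(fits, "exponent"), "empty")
})

test_that("Spearman-with-shuffle behaves on monotone and independent pairs", {
  set.seed(6)
  x <- sort(rnorm(100))
  out <- spearman_with_shuffle(x, exp(x), n_shuffle = 50)
  expect_equal(out$rho, 1)
  # permutation null: mean ~ 0, SD ~ 1/sqrt(n-1)
  out2 <- spearman_with_shuffle(rnorm(100), rnorm(100), n_shuffle = 400)
  expect_lt(abs(mean(out2$null_rho)), 0.02)
  expect_equal(sd(out2$null_rho), 1 / sqrt(99), tolerance = 0.15)
  expect_null(spearman_with_shuffle(1:2, 2:1))
})

test_that("pointwise PSD tests use the 0.05/3 threshold and localize shifts", {
  set.seed(7)
  nbin <- 30
  a <- matrix(rnorm(40 * nbin), 40)
  b <- matrix(rnorm(40 * nbin), 40)
  b[, 12] <- b[, 12] + 10
  res <- pointwise_psd_test(a, b)
  expect_equal(res$threshold, 0.05 / 3)
  expect_true(res$significant[12])
  expect_lt(sum(res$significant[-12]), 3)
  # untestable bins are NA
  a2 <- a; a2[2:40, 5] <- NA
  res2 <- pointwise_psd_test(a2, b)
  expect_true(is.na(res2$p[5]))
})
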