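#' Members of a named predictor family
#'
#' Families of four predictors entered jointly into the GLMs: `DeF`
#' (demography: LD, Ag, DD, Gd), `ApF` (aperiodic: LO, SO, LE, SE), `PeF`
#' (periodic: LCF, SCF, LP, SP), `LFPF` (LO, LE, LCF, LP), `SPKF` (SO, SE,
#' SCF, SP), and `LSF` (LFP-SPK differences: LSCF, LSP, LSO, LSE).
#'
#' @param family Family name.
#' @return Character vector of 4 predictor names.
#' @export
family_members <- function(family) {
  fam <- list(DeF = c("LD", "Ag", "DD", "Gd"),
              ApF = c("LO", "SO", "LE", "SE"),
              PeF = c("LCF", "SCF", "LP", "SP"),
              LFPF = c("LO", "LE", "LCF", "LP"),
              SPKF = c("SO", "SE", "SCF", "SP"),
              LSF = c("LSCF", "LSP", "LSO", "LSE"))
  if (!family %in% names(fam)) stop("unknown family: ", family)
  fam[[family]]
}

#' Validate derived-column consistency of a clinical table
#'
#' The difference columns must satisfy LSCF = LCF - SCF, LSP = LP - SP,
#' LSO = LO - SO, LSE = LE - SE. A violation is a data error and stops.
#'
#' @param table Clinical data.frame.
#' @param tol Numerical tolerance.
#' @return `table`, invisibly.
#' @export
check_clinical_table <- function(table, tol = 1e-8) {
  pairs <- list(LSCF = c("LCF", "SCF"), LSP = c("LP", "SP"),
                LSO = c("LO", "SO"), LSE = c("LE", "SE"))
  for (nm in names(pairs)) {
    if (!all(c(nm, pairs[[nm]]) %in% names(table))) next
    d <- table[[nm]] - (table[[pairs[[nm]][1]]] - table[[pairs[[nm]][2]]])
    if (any(abs(d) > tol, na.rm = TRUE)) {
      stop("derived-column inconsistency in ", nm)
    }
  }
  invisible(table)
}

z_norm <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

# Design matrix (without intercept) for a family at a given interaction
# order, built from z-normalized members.
family_design <- function(table, members, order) {
  X <- vapply(members, function(m) z_norm(table[[m]]), numeric(nrow(table)))
  colnames(X) <- members
  if (order == "zeroth") return(X)
  if (order == "first") {
    cmb <- utils::combn(4, 2)
    out <- sapply(seq_len(ncol(cmb)), function(j) X[, cmb[1, j]] * X[, cmb[2, j]])
    colnames(out) <- apply(cmb, 2, function(ij) paste(members[ij], collapse = ":"))
    return(out)
  }
  if (order == "higher") {
    cmb3 <- utils::combn(4, 3)
    out <- sapply(seq_len(ncol(cmb3)), function(j) {
      X[, cmb3[1, j]] * X[, cmb3[2, j]] * X[, cmb3[3, j]]
    })
    colnames(out) <- apply(cmb3, 2, function(ijk) paste(members[ijk], collapse = ":"))
    quad <- X[, 1] * X[, 2] * X[, 3] * X[, 4]
    out <- cbind(out, quad)
    colnames(out)[5] <- paste(members, collapse = ":")
    return(out)
  }
  stop("unknown order: ", order)
}

glm_aic <- function(fit) {
  n <- length(fit$residuals)
  rss <- sum(fit$residuals^2)
  k <- length(stats::coef(fit)) + 1  # + residual variance
  n * log(rss / n) + 2 * k
}

#' Fit a predictor-family GLM at a given interaction order
#'
#' Gaussian-identity linear model on z-normalized predictors and response:
#' `individual` (one predictor), `zeroth` (the 4 family members), `first`
#' (the 6 pairwise products), or `higher` (4 triple products + the
#' quadruple product). Reports R-squared, a likelihood-based AIC
#' (`n log(RSS/n) + 2k`, `k` counting intercept and variance), the model
#' F-test against the intercept-only model, and per-coefficient p-values.
#'
#' @param table Clinical data.frame (validated for derived-column
#'   consistency).
#' @param family Family name (see [family_members()]); for
#'   `order = "individual"` the name of a single predictor.
#' @param response Response column name.
#' @param order `"individual"`, `"zeroth"`, `"first"`, or `"higher"`.
#' @param phenotype `"all"` or a value of `table$phenotype` to subset.
#' @return List of class `model_result`: `r_squared`, `aic`, `model_p`,
#'   `coefficients` (data.frame term/estimate/se/p), `n_obs`,
#'   `rank_deficient`.
#' @export
fit_family <- function(table, family, response,
                       order = c("zeroth", "first", "higher", "individual"),
                       phenotype = "all") {
  order <- match.arg(order)
  check_clinical_table(table)
  if (phenotype != "all" && "phenotype" %in% names(table)) {
    table <- table[table$phenotype == phenotype, , drop = FALSE]
  }
  if (order == "individual") {
    members <- family
    X <- matrix(z_norm(table[[family]]), ncol = 1,
                dimnames = list(NULL, family))
  } else {
    members <- family_members(family)
    X <- family_design(table, members, order)
  }
  y <- table[[response]]
  cc <- stats::complete.cases(cbind(X, y))
  X <- X[cc, , drop = FALSE]
  y <- z_norm(y[cc])
  n <- length(y)
  if (n < ncol(X) + 2) stop("too few complete cases (", n, ") for ",
                            ncol(X), " terms")
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  rank_def <- any(is.na(stats::coef(fit)))
  sm <- summary(fit)
  f <- sm$fstatistic
  model_p <- if (!is.null(f)) stats::pf(f[1], f[2], f[3], lower.tail = FALSE) else NA_real_
  coefs <- data.frame(term = rownames(sm$coefficients),
                      estimate = sm$coefficients[, 1],
                      se = sm$coefficients[, 2],
                      p = sm$coefficients[, 4], row.names = NULL)
  structure(list(family = if (order == "individual") NA_character_ else family,
                 response = response, order = order,
                 r_squared = sm$r.squared,
                 aic = if (rank_def) NA_real_ else glm_aic(fit),
                 model_p = unname(model_p), coefficients = coefs,
                 n_obs = n, rank_deficient = rank_def),
            class = "model_result")
}

#' Two-factor ANOVA of aperiodic parameters (signal x subregion)
#'
#' N-way analysis of variance with interaction on the (unbalanced) table of
#' per-trajectory aperiodic fits, using Type II sums of squares, plus
#' Bonferroni-corrected pairwise comparisons between the six
#' stream-by-subregion cells.
#'
#' @param fits data.frame with columns `stream`, `subregion` and the value
#'   column.
#' @param value Which parameter to analyze (`"exponent"` or `"offset"`).
#' @return List: `p_signal`, `p_subregion`, `p_interaction`, `posthoc`
#'   (pairwise p-value matrix).
#' @export
anova_aperiodic <- function(fits, value = c("exponent", "offset")) {
  value <- match.arg(value)
  d <- data.frame(y = fits[[value]],
                  stream = factor(fits$stream),
                  subregion = factor(fits$subregion))
  d <- d[stats::complete.cases(d), ]
  tab <- table(d$stream, d$subregion)
  if (any(tab == 0)) stop("empty stream x subregion cell")
  fit <- stats::lm(y ~ stream * subregion, data = d)
  a2 <- car::Anova(fit, type = 2)
  p <- a2[["Pr(>F)"]]
  rn <- rownames(a2)
  cell <- interaction(d$stream, d$subregion)
  ph <- stats::pairwise.t.test(d$y, cell, p.adjust.method = "bonferroni")
  list(p_signal = p[rn == "stream"],
       p_subregion = p[rn == "subregion"],
       p_interaction = p[rn == "stream:subregion"],
       posthoc = ph$p.value)
}

#' Spearman correlation with a permutation null
#'
#' Spearman's rho on the observed pairing of parameters from simultaneously
#' recorded sites, plus the null distribution of rho under `n_shuffle`
#' random permutations of one member.
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs).
#' @param n_shuffle Number of permutations (default 100).
#' @return List: `rho`, `null_rho` (length `n_shuffle`), `p_perm`
#'   (two-sided permutation p-value), `n`.
#' @export
spearman_with_shuffle <- function(x, y, n_shuffle = 100) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(NULL)
  rho <- stats::cor(x, y, method = "spearman")
  null_rho <- vapply(seq_len(n_shuffle), function(i) {
    stats::cor(x, sample(y), method = "spearman")
  }, numeric(1))
  p_perm <- (1 + sum(abs(null_rho) >= abs(rho))) / (n_shuffle + 1)
  list(rho = rho, null_rho = null_rho, p_perm = p_perm, n = n)
}

#' Per-frequency two-group comparison with Bonferroni correction
#'
#' Two-tailed Wilcoxon rank-sum test at every frequency bin between two
#' groups of PSDs, significant where `p < alpha / correction_groups`
#' (default 0.05/3, the three pairwise subregion contrasts).
#'
#' @param a,b Matrices (observations x frequency bins) for the two groups.
#' @param correction_groups Bonferroni divisor (default 3).
#' @param alpha Nominal level (default 0.05).
#' @return List: `p` (per bin; NA where untestable), `significant` (logical
#'   mask), `threshold`.
#' @export
pointwise_psd_test <- function(a, b, correction_groups = 3, alpha = 0.05) {
  stopifnot(ncol(a) == ncol(b))
  thr <- alpha / correction_groups
  p <- vapply(seq_len(ncol(a)), function(j) {
    x <- a[, j][is.finite(a[, j])]
    y <- b[, j][is.finite(b[, j])]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided")$p.value)
  }, numeric(1))
  list(p = p, significant = !is.na(p) & p < thr, threshold = thr)
}
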