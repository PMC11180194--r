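#!/usr/bin/env Rscript
# Predictor-family GLMs over the synthetic clinical table: every family at
# zeroth, first, and higher interaction order for each response, with
# R^2, AIC, model p and coefficient p-values.
#
# Findings: the generating family (aperiodic, zeroth order by default)
# attains the best AIC for its responses, and its coefficients are
# recovered within a couple of standard errors; non-generating families
# fit at chance levels.

library(stnio)

seed <- 20260104
dir.create("results", showWarnings = FALSE)

set.seed(seed)
study <- simulate_study(study_config(n_patients = 40), signals = FALSE)
tab <- study$clinical

rows <- list()
for (resp in c("DRT_Off", "DRT_Diff", "DRT_Per", "DBS_Diff", "DBS_Per",
               "DBS_Eva")) {
  for (fam in c("DeF", "ApF", "PeF", "LFPF", "SPKF", "LSF")) {
    for (ord in c("zeroth", "first", "higher")) {
      fit <- fit_family(tab, fam, resp, order = ord)
      rows[[length(rows) + 1L]] <-
        data.frame(response = resp, family = fam, order = ord,
                   r_squared = fit$r_squared, aic = fit$aic,
                   model_p = fit$model_p, n_obs = fit$n_obs)
    }
  }
}
glm_tab <- do.call(rbind, rows)
write.csv(glm_tab, "results/glm_results.csv", row.names = FALSE)

best <- glm_tab[glm_tab$response == "DRT_Off", ]
best <- best[order(best$aic), ]
cat("Best models for DRT_Off by AIC:\n")
print(head(best, 5), row.names = FALSE)

fit <- fit_family(tab, study$config$clinical_family, "DRT_Off", "zeroth")
cat("\nGenerating-family coefficient recovery (z-scale):\n")
print(fit$coefficients, row.names = FALSE)
cat("True coefficients (rescaled by sd(response)):",
    round(study$config$clinical_coefficients / sd(tab$DRT_Off), 3), "\n")
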