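#!/usr/bin/env Rscript
# Full pipeline over a synthetic study: NRMS/outliers, Welch NPSDs, per-site
# spectral parameterization, whitening, safe-boundary subregion averages,
# beta center frequencies, downshift, and the aperiodic ANOVA.
#
# Findings: the fitted exponents separate the streams as generated
# (LFP ~2.2 vs SPK ~0.1, signal-effect p << 1e-10); the whitened
# motor-domain betaCFs recover the generator's values and the SPK betaCF is
# downshifted relative to LFP in essentially all trajectories.

library(stnio)
library(jsonlite)

seed <- 20260103
dir.create("results", showWarnings = FALSE)

set.seed(seed)
study <- simulate_study(study_config(
  n_patients = 8, n_trajectories = 1,
  subregion_lengths = c(pre = 4, motor = 2, nonmotor = 2)))
res <- run_pipeline(study)

write.csv(res$fits, "results/aperiodic_fits.csv", row.names = FALSE)
write.csv(res$beta, "results/beta_cf.csv", row.names = FALSE)
write.csv(res$counts, "results/site_counts.csv", row.names = FALSE)
write_json(list(downshift = unclass(res$downshift),
                downshift_z = unclass(res$downshift_z),
                anova_exponent = res$anova_exponent[c("p_signal", "p_subregion",
                                                      "p_interaction")],
                anova_offset = res$anova_offset[c("p_signal", "p_subregion",
                                                  "p_interaction")]),
           "results/pipeline_summary.json", auto_unbox = TRUE, digits = NA)

agg <- aggregate(exponent ~ stream, data = res$fits, FUN = mean)
cat("Mean fitted exponent by stream:\n"); print(agg, row.names = FALSE)
cat("ANOVA signal-effect p (exponent):",
    format(res$anova_exponent$p_signal, digits = 3), "\n")
cat("Downshift fractions (down/up/equal):",
    round(c(res$downshift$fraction_down, res$downshift$fraction_up,
            res$downshift$fraction_equal), 3), "\n")
cat("Signed-rank p for LFP > SPK betaCF:",
    format(res$downshift$p_value, digits = 3), "\n")
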