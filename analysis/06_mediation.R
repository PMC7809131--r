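#!/usr/bin/env Rscript
# Stage 6 — mediation of exposure effects on growth and cognition.
#
# For each outcome (WHO growth z-scores, FTII novelty preference) and each
# 2-week factor score: the single-mediator product-of-coefficients model
# (standardized, smoking handled as an exogenous correlate) and the joint
# three-mediator model, with Sobel z-tests; the headline single-factor
# models additionally get bias-corrected bootstrap 95 % CIs.

library(exmirpae)

dir <- "results/synthetic"
meta <- read.csv(file.path(dir, "metadata.csv"))
scores_raw <- read.delim(file.path(dir, "factor_scores_T2wk.tsv"))
d <- merge(meta[meta$timepoint == "T2wk", ], scores_raw, by = "sample_id")
factor_cols <- grep("^F", names(scores_raw), value = TRUE)
outcomes <- c("weight_z", "length_z", "hc_z", "ftii_novelty")

battery <- run_mediation_battery(d, factor_cols, outcomes)
write.table(battery, file.path(dir, "mediation_battery_T2wk.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

single <- battery[battery$model == "single", ]
cat("Single-mediator models (2-week factors):\n")
print(single[, c("outcome", "mediator", "a", "b", "c_prime", "indirect",
                 "p_indirect")], digits = 3)

# BC bootstrap for the factor with the strongest indirect path per outcome
for (y in outcomes) {
  rows <- single[single$outcome == y, ]
  best <- rows[which.max(abs(rows$indirect)), ]
  des <- mediation_design("aa_per_day", best$mediator, y,
                          covariate = "cigarettes_per_day")
  ci <- bootstrap_indirect_ci(des, d, n_boot = 2000, seed = 20260106)
  cat(sprintf("%s via %s: indirect %.3f, BC 95%% CI [%.3f, %.3f] -> %s\n",
              y, best$mediator, ci$point, ci$ci[1], ci$ci[2],
              ci$classification))
}
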