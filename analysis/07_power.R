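#!/usr/bin/env Rscript
# Stage 7 — Monte Carlo power, coverage and bias studies.
#
# CFA study: 3-factor population with loadings 0.50, factor correlations
# 0.50, residual variances 0.75, n = 59, default 8/5/5 item allocation,
# with a sensitivity sweep over allocations. Mediation study: standardized
# paths 0.40 at n = 58. 1000 replications per condition here; pass
# n_reps = 10000 for the full-scale study.

library(exmirpae)

dir <- "results/synthetic"
reps <- 1000

cp <- simulate_cfa_power(n_reps = reps, n = 59, seed = 20260107)
g <- cp$groups
cat(sprintf("CFA power study (8/5/5, %d/%d converged):\n",
            cp$n_converged, cp$n_reps))
cat(sprintf("  loading power %.1f-%.1f%%, factor-cov power %.1f-%.1f%%\n",
            100 * min(cp$power[g == "loading"]),
            100 * max(cp$power[g == "loading"]),
            100 * min(cp$power[g == "factor_cov"]),
            100 * max(cp$power[g == "factor_cov"])))
cat(sprintf("  coverage %.1f-%.1f%%, max |bias| %.2f%%\n",
            100 * min(cp$coverage[g != "residual_var"]),
            100 * max(cp$coverage[g != "residual_var"]),
            max(abs(cp$percent_bias[g != "residual_var"]))))

sweep <- lapply(list(c(8, 5, 5), c(6, 6, 6), c(8, 7, 7)), function(sz) {
  r <- simulate_cfa_power(default_power_cfa_spec(sz), n_reps = reps %/% 2,
                          n = 59, seed = 20260108)
  data.frame(allocation = paste(sz, collapse = "/"),
             load_power_min = min(r$power[r$groups == "loading"]),
             phi_power_min = min(r$power[r$groups == "factor_cov"]),
             phi_power_max = max(r$power[r$groups == "factor_cov"]))
})
sweep <- do.call(rbind, sweep)
write.table(sweep, file.path(dir, "cfa_power_allocation_sweep.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Allocation sensitivity:\n"); print(sweep, digits = 3)

mp <- simulate_mediation_power(n_reps = reps, seed = 20260109)
cat(sprintf("Mediation power study: path power %.1f-%.1f%%, Sobel indirect %.1f%%\n",
            100 * min(mp$power[c("a", "b", "c_prime")]),
            100 * max(mp$power[c("a", "b", "c_prime")]),
            100 * mp$power[["indirect"]]))
cat(sprintf("  coverage %.1f-%.1f%%, max |bias| %.2f%% (absolute %.4f)\n",
            100 * min(mp$coverage), 100 * max(mp$coverage),
            max(abs(mp$percent_bias)),
            max(abs(mp$percent_bias / 100 * mp$truth))))

jsonlite::write_json(
  list(cfa = cp[c("n_reps", "n_converged", "power", "coverage",
                  "percent_bias")],
       mediation = mp[c("n_reps", "power", "coverage", "percent_bias")]),
  file.path(dir, "power_results.json"), auto_unbox = TRUE, digits = NA)
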