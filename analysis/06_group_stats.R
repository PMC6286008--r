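#!/usr/bin/env Rscript
# Stage 6: apnea-vs-baseline statistics per lag.
#
# Normality-gated hypothesis tests and single-feature ROC analysis for
# every descriptor and lag, plus the pooled SDratio/R/CCM correlations.

library(regpoincare)

sweep <- read.csv("results/poincare_features.csv")

tab <- compare_by_tau(sweep)
write.csv(tab, "results/significance_by_tau.csv", row.names = FALSE)

cat("lags with Bonferroni-significant (p < 0.025) separation:\n")
for (f in unique(tab$feature)) {
  sig <- tab$tau[tab$feature == f & tab$significant_bonferroni]
  cat(sprintf("  %-8s %3d lags%s\n", f, length(sig),
              if (length(sig)) sprintf(" (tau %d..%d)", min(sig), max(sig))
              else ""))
}
best <- tab[tab$feature %in% c("SDratio", "R", "CCM"), ]
best <- best[order(best$p_value), ][1:3, ]
cat("\nstrongest separations:\n")
print(best[, c("feature", "tau", "p_value", "auc")], digits = 3)

fc <- feature_correlations(sweep)
write.csv(as.data.frame(fc$r), "results/feature_correlations.csv")
cat(sprintf("\npooled over %d rows: cor(SDratio, R) = %.3f, cor(SDratio, CCM) = %.3f\n",
            fc$n_rows, fc$r["SDratio", "R"], fc$r["SDratio", "CCM"]))
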