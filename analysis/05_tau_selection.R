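#!/usr/bin/env Rscript
# Stage 5: embedding-lag criteria.
#
# The eight literature criteria aggregated over segments, plus the
# knee of the CCM-vs-tau curve as an upper bound for useful lags.

library(regpoincare)

manifest <- read.csv("results/filtered_manifest.csv")
segs <- lapply(file.path("results/filtered", manifest$file),
               read_segment_csv)

ct <- criteria_table(segs, max_lag = 200)
tab <- cbind(stat = rownames(ct$table), ct$table)
write.csv(tab, "results/tau_criteria.csv", row.names = FALSE)
cat("lag-selection criteria over segments (samples):\n")
print(ct$table, digits = 3)
cat(sprintf("\nrecommended sweep upper bound: %d samples\n",
            ct$recommended_max_tau))

sweep <- read.csv("results/poincare_features.csv")
med_ccm <- vapply(sort(unique(sweep$tau)), function(tt)
  median(sweep$CCM[sweep$tau == tt], na.rm = TRUE), numeric(1))
knee <- ccm_inflection(med_ccm)
cat(sprintf("CCM-curve knee (decrease -> plateau): tau = %d samples\n",
            knee))
cat(sprintf("ACF second-derivative criterion mean: %.1f samples\n",
            ct$table["mean", "acf_second_deriv_sign_change"]))
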