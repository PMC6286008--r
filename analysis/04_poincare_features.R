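#!/usr/bin/env Rscript
# Stage 4: lagged Poincare descriptors.
#
# SD1, SD2, SDarea, SDratio, R and CCM for every segment at every lag
# tau = 1..70 samples (0.004-0.28 s at 250 Hz).

library(regpoincare)

manifest <- read.csv("results/filtered_manifest.csv")
segs <- lapply(file.path("results/filtered", manifest$file),
               read_segment_csv)

sweep <- feature_sweep(segs, 1:70)
write.csv(sweep, "results/poincare_features.csv", row.names = FALSE)

cat(sprintf("computed %d descriptor rows (%d segments x %d lags)\n",
            nrow(sweep), length(segs), 70))
cat("\nmedians at tau = 5:\n")
s5 <- sweep[sweep$tau == 5, ]
print(aggregate(s5[, c("SD1", "SD2", "SDratio", "R", "CCM")],
                list(label = s5$label), median), digits = 3)
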