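#!/usr/bin/env Rscript
# Stage 1: simulate the study dataset.
#
# 29 apnea + 24 baseline REG segments of 16 s at 250 Hz, mean pulse
# period 0.99 s (between-segment SD 0.12 s), pulse ranges near
# 0.092 / 0.099 ohm. One CSV per segment under results/segments/.

library(regpoincare)

seed <- 1
out_dir <- "results/segments"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

segs <- generate_dataset(n_apnea = 29, n_baseline = 24,
                         segment_seconds = 16, seed = seed)

manifest <- data.frame(file = sprintf("seg%02d.csv", seq_along(segs)),
                       label = vapply(segs, `[[`, character(1), "label"))
for (i in seq_along(segs))
  write_segment_csv(segs[[i]], file.path(out_dir, manifest$file[i]))
write.csv(manifest, "results/segment_manifest.csv", row.names = FALSE)

cat(sprintf("wrote %d segments (%d apnea, %d baseline) to %s\n",
            length(segs), sum(manifest$label == "apnea"),
            sum(manifest$label == "baseline"), out_dir))
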