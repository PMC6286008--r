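#!/usr/bin/env Rscript
# Stage 2: band-limit and artifact-screen the raw segments.
#
# Each record is filtered (0.1 Hz Chebyshev-II high-pass + 20 Hz
# low-pass, zero phase) and the automatic artifact screen keeps the
# clean 16-s windows. Filtered segments go to results/filtered/.

library(regpoincare)

manifest <- read.csv("results/segment_manifest.csv")
out_dir <- "results/filtered"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

kept <- character(0)
for (f in manifest$file) {
  rec <- read_segment_csv(file.path("results/segments", f))
  segs <- select_segments(bandlimit(rec), segment_seconds = 16)
  if (length(segs) == 1) {
    write_segment_csv(segs[[1]], file.path(out_dir, f))
    kept <- c(kept, f)
  }
}

cat(sprintf("kept %d / %d segments after the artifact screen\n",
            length(kept), nrow(manifest)))
write.csv(manifest[manifest$file %in% kept, ],
          "results/filtered_manifest.csv", row.names = FALSE)
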