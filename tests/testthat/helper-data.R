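# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# The default synthetic study: 29 apnea + 24 baseline band-limited 16-s
# segments at 250 Hz, master seed 1.
default_dataset <- function() {
  if (is.null(.fixture_cache$dataset)) {
    segs <- generate_dataset(29, 24, segment_seconds = 16, seed = 1)
    .fixture_cache$dataset <- lapply(segs, bandlimit)
  }
  .fixture_cache$dataset
}

# Descriptor sweep of the default dataset over lags 1..70.
default_sweep <- function() {
  if (is.null(.fixture_cache$sweep))
    .fixture_cache$sweep <- feature_sweep(default_dataset(), 1:70)
  .fixture_cache$sweep
}

# Noise-free, jitter-free periodic pulse train.
clean_train <- function(period = 1.0, duration = 16, range = 0.1) {
  generate_record(synth_config(
    duration = duration, period_mean = period, period_jitter_sd = 0,
    pulse_range_mean = range, amplitude_jitter_sd = 0,
    drift_amplitude = 0, noise_sd = 0, seed = 1))
}

# Independent brute-force CCM oracle: per-triplet shoelace area via the
# cross product of edge vectors, explicit loop, stats::sd.
ccm_oracle <- function(x, tau) {
  n <- length(x)
  xs <- x[seq_len(n - tau)]
  ys <- x[(tau + 1):n]
  m <- n - tau
  tot <- 0
  for (i in seq_len(m - 2)) {
    tot <- tot + 0.5 * abs(
      (xs[i + 1] - xs[i]) * (ys[i + 2] - ys[i]) -
      (xs[i + 2] - xs[i]) * (ys[i + 1] - ys[i]))
  }
  sd1 <- stats::sd((xs - ys) / sqrt(2))
  sd2 <- stats::sd((xs + ys) / sqrt(2))
  tot / (pi * sd1 * sd2 * (m - 2))
}
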