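fs <- 250

test_that("landmarks on a clean 1-s train are exactly periodic", {
  rec <- clean_train(period = 1.0)
  lm <- detect_landmarks(rec)
  expect_equal(unique(diff(lm$maxima)), 250)
  expect_gte(length(lm$maxima), 14)
  # alternation: each maximum strictly between its flanking minima
  expect_true(all(lm$maxima > head(lm$minima, -1) &
                  lm$maxima < tail(lm$minima, -1)))
})

test_that("mild noise leaves landmark count and spacing stable", {
  # the detector contract takes band-limited input
  rec <- clean_train(period = 1.0, range = 0.1)
  set.seed(21)
  noisy <- rec
  noisy$samples <- rec$samples + rnorm(length(rec$samples), 0, 0.001)
  lm0 <- detect_landmarks(bandlimit(rec))
  lm1 <- detect_landmarks(bandlimit(noisy))
  expect_lte(abs(length(lm1$maxima) - length(lm0$maxima)), 1)
  expect_true(all(abs(diff(lm1$maxima) - 250) <= 2))
})

test_that("pure sine geometry matches closed-form symmetry", {
  a <- 0.05
  # small phase offset avoids exact ties at the sampled extrema
  x <- a * sin(2 * pi * (0:3999) / 250 + 0.1)
  lm <- detect_landmarks(x, fs = fs)
  # maxima at the analytic sine peaks within one sample: 1-based index
  # 1 + (pi/2 - 0.1) / (2 pi) * 250 + 250 k = 59.52 + 250 k
  expect_true(all(abs(lm$maxima - 59.52 - 250 *
                        round((lm$maxima - 59.52) / 250)) <= 1))
  g <- compute_geometry(x, lm, fs = fs)
  expect_lte(abs(g$dt_max - 250), 1)
  expect_lte(abs(g$dt_min - 250), 1)
  expect_lte(abs(g$dt_min_max - 125), 1)
  expect_equal(g$alpha, 2 * a / 125, tolerance = 0.02)
  expect_equal(g$Range, 2 * a, tolerance = 1e-3)
})

test_that("geometry recovers the configured pulse range", {
  rec <- generate_record(synth_config(
    duration = 16, pulse_range_mean = 0.1, period_jitter_sd = 0,
    amplitude_jitter_sd = 0, drift_amplitude = 0, noise_sd = 0,
    seed = 3))
  g <- compute_geometry(rec)
  expect_equal(g$Range, 0.1, tolerance = 1e-6)
})

test_that("flat or near-empty signals raise insufficient-pulses", {
  expect_error(detect_landmarks(rep(0.2, 4000), fs = fs),
               class = "regpoincare_insufficient_pulses_error")
  expect_error(detect_landmarks(rnorm(50), fs = fs),
               class = "regpoincare_insufficient_pulses_error")
})

test_that("amplitude features shift/scale as dimensional analysis demands", {
  rec <- bandlimit(generate_record(synth_config(duration = 16, seed = 8)))
  g0 <- compute_geometry(rec)
  shifted <- rec
  shifted$samples <- rec$samples + 0.7
  g1 <- compute_geometry(shifted)
  expect_equal(g1$Range, g0$Range, tolerance = 1e-9)
  expect_equal(g1$alpha, g0$alpha, tolerance = 1e-9)
  expect_equal(g1$d_max, g0$d_max, tolerance = 1e-9)
  expect_equal(g1$d_range, g0$d_range, tolerance = 1e-9)
  scaled <- rec
  scaled$samples <- rec$samples * 2
  g2 <- compute_geometry(scaled)
  for (f in c("Max", "Min", "Range", "alpha", "Area", "d_max", "d_range"))
    expect_equal(g2[[f]], 2 * g0[[f]], tolerance = 1e-9)
  expect_equal(g2$dt_min_max, g0$dt_min_max)
})

test_that("segment areas sit in the expected order of magnitude", {
  segs <- default_dataset()[1:10]
  areas <- vapply(segs, function(s) compute_geometry(s)$Area, numeric(1))
  expect_true(all(areas > 5 & areas < 25))
})

test_that("group comparison flags separated ranges and not null data", {
  mk <- function(range, n, seed) {
    segs <- generate_dataset(n, 0, segment_seconds = 8, seed = seed,
      base_config = synth_config(pulse_range_mean = range,
                                 pulse_range_sd = 0.005,
                                 regime_modulation = 0))
    do.call(rbind, lapply(segs, compute_geometry))
  }
  lo <- mk(0.05, 10, 31)
  hi <- mk(0.15, 10, 32)
  cmp <- compare_geometry(hi, lo)
  expect_lt(cmp$p_value[cmp$feature == "Range"], 0.001)

  # null: identical configuration in both groups
  null_rejections <- vapply(1:5, function(r) {
    a <- mk(0.095, 8, 100 + r)
    b <- mk(0.095, 8, 200 + r)
    sum(compare_geometry(a, b)$p_value < 0.05)
  }, numeric(1))
  # 10 features x 5 replicates at level 0.05: expect few rejections
  expect_lte(sum(null_rejections), 6)
  expect_error(compare_geometry(lo[1, ], hi),
               class = "regpoincare_insufficient_data_error")
})
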