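test_that("embedding pairs the signal with its lagged copy", {
  p <- poincare_embed(1:4, 1)
  expect_equal(p$x, c(1, 2, 3))
  expect_equal(p$y, c(2, 3, 4))
  expect_equal(poincare_embed(rnorm(4000), 70)$n_points, 3930)
  x <- rnorm(10)
  expect_error(poincare_embed(x, 9),
               class = "regpoincare_lag_error")
  expect_error(poincare_embed(x, 0),
               class = "regpoincare_lag_error")
})

test_that("sd features match a hand-computed alternating series", {
  p <- poincare_embed(c(0, 1, 0, 1, 0), 1)
  f <- sd_features(p, components = c("sd1", "sd2"))
  # differences/sqrt(2) alternate +-1/sqrt(2): sample var = 2/3
  expect_equal(f$sd1, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(f$sd2, 0)
  expect_error(sd_features(p),
               class = "regpoincare_degenerate_plot_error")
})

test_that("rotation preserves total variance on random plots", {
  set.seed(7)
  for (i in 1:50) {
    x <- rnorm(sample(20:200, 1))
    p <- poincare_embed(x, sample(1:3, 1))
    f <- sd_features(p, components = c("sd1", "sd2"))
    expect_equal(f$sd1^2 + f$sd2^2, var(p$x) + var(p$y),
                 tolerance = 1e-10)
  }
})

test_that("lag correlation matches sinusoid phase geometry", {
  t <- 0:2999
  x <- sin(2 * pi * t / 250)
  expect_lt(abs(correlation_r(poincare_embed(x, 63))), 0.02)  # T/4
  expect_lt(abs(correlation_r(poincare_embed(x, 125)) + 1), 0.01)  # T/2
  p <- poincare_plot(x[1:100], x[1:100], 0L)
  expect_equal(correlation_r(p), 1)
  expect_error(correlation_r(poincare_plot(rep(1, 10), rnorm(10), 1L)),
               class = "regpoincare_degenerate_plot_error")
})

test_that("collinear triplets contribute zero CCM area", {
  # first triplet (0,0),(1,1),(2,2) is collinear; only the second
  # triplet (1,1),(2,2),(5,0), with shoelace area 2.5, contributes
  p <- poincare_plot(c(0, 1, 2, 5), c(0, 1, 2, 0), 1L)
  f <- sd_features(p, components = c("sd1", "sd2"))
  expect_equal(ccm(p), 2.5 / (pi * f$sd1 * f$sd2 * 2),
               tolerance = 1e-12)
})

test_that("CCM is invariant to affine amplitude transforms", {
  set.seed(8)
  x <- rnorm(300)
  base <- ccm(x, tau = 2)
  expect_equal(ccm(3.7 * x + 11, tau = 2), base, tolerance = 1e-9)
  expect_equal(ccm(-0.2 * x - 5, tau = 2), base, tolerance = 1e-9)
})

test_that("CCM equals the brute-force shoelace oracle", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(10:50, 1))
    tau <- sample(1:3, 1)
    expect_equal(ccm(x, tau = tau), ccm_oracle(x, tau),
                 tolerance = 1e-12)
  }
})

test_that("degenerate plots raise errors; sweeps record them as NA", {
  expect_error(ccm(rep(1, 20), tau = 1),
               class = "regpoincare_degenerate_plot_error")
  segs <- list(structure(list(samples = rep(0.5, 100),
                              sampling_rate = 250, label = "apnea",
                              source_offset = 0L),
                         class = "reg_segment"),
               generate_dataset(0, 1, segment_seconds = 1, seed = 4)[[1]])
  w <- capture_warnings(sw <- feature_sweep(segs, 1:3))
  expect_length(w, 3)  # one per degenerate (segment, tau) pair
  expect_true(all(grepl("recorded as NA", w)))
  expect_equal(nrow(sw), 6)
  expect_true(all(is.na(sw$SDratio[sw$segment_id == 1])))
  expect_true(all(is.finite(sw$SDratio[sw$segment_id == 2])))
})

test_that("sweep dimensions and reproducibility", {
  segs <- generate_dataset(2, 2, segment_seconds = 4, seed = 6)
  s1 <- feature_sweep(segs, c(1, 5, 9))
  expect_equal(nrow(s1), 12)
  expect_equal(names(s1), c("segment_id", "label", "tau", "SD1", "SD2",
                            "SDarea", "SDratio", "R", "CCM"))
  expect_identical(s1, feature_sweep(segs, c(1, 5, 9)))
  expect_equal(nrow(feature_sweep(list(), 1:5)), 0)
})

test_that("circular embedding links SDratio to R", {
  # on a circularly rolled pair var(x) = var(y) exactly, so
  # sd_ratio^2 = (1 - r) / (1 + r)
  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(100)
    tau <- sample(1:10, 1)
    y <- c(x[(tau + 1):100], x[1:tau])
    p <- poincare_plot(x, y, tau)
    f <- sd_features(p)
    r <- correlation_r(p)
    expect_equal(f$sd_ratio^2, (1 - r) / (1 + r), tolerance = 1e-10)
  }
})
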