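make_features <- function(n_per_class, shift, seed) {
  set.seed(seed)
  data.frame(SDratio = c(rnorm(n_per_class, shift), rnorm(n_per_class)),
             R = c(rnorm(n_per_class, -shift), rnorm(n_per_class)),
             CCM = c(rnorm(n_per_class, shift / 2), rnorm(n_per_class)))
}
labels2 <- function(n) rep(c("apnea", "baseline"), each = n)

test_that("input combinations exclude the SDratio+R pair", {
  combos <- input_combos()
  expect_length(combos, 5)
  expect_false(any(vapply(combos, function(cc)
    all(c("SDratio", "R") %in% cc), logical(1))))
  expect_error(
    loocv_evaluate("logistic", c("SDratio", "R"),
                   make_features(5, 1, 1), labels2(5)),
    class = "regpoincare_config_error")
})

test_that("relief weights: constant features get zero, informative beat noise", {
  X <- cbind(sep = rep(c(0, 1), each = 20), flat = rep(0.3, 40))
  set.seed(19)
  X <- cbind(X, noise = runif(40))
  w <- relief_weights(X, labels2(20))
  expect_equal(unname(w["flat"]), 0)
  expect_gt(w["sep"], w["noise"])
  expect_gt(w["sep"], 0.5)
  # label-independent features under permuted labels: weights near 0
  set.seed(20)
  null_w <- replicate(20, {
    Xr <- matrix(rnorm(80), ncol = 2)
    relief_weights(Xr, sample(labels2(20)))
  })
  expect_true(all(abs(null_w) < 0.25))
  expect_lt(abs(mean(null_w)), 0.1)
  expect_error(relief_weights(X, rep("apnea", 40)),
               class = "regpoincare_class_error")
})

test_that("all four classifiers are perfect on separable data", {
  ft <- make_features(12, 8, 21)
  for (kind in c("logistic", "naive_bayes", "svm_linear", "cart")) {
    rep_ <- loocv_evaluate(kind, "SDratio", ft, labels2(12))
    expect_equal(rep_$accuracy, 1)
    expect_equal(rep_$auc, 1)
    rep2 <- loocv_evaluate(kind, c("R", "CCM"), ft, labels2(12))
    expect_equal(rep2$accuracy, 1)
  }
})

test_that("leave-one-out is deterministic", {
  ft <- make_features(10, 1, 22)
  a <- loocv_evaluate("cart", c("SDratio", "CCM"), ft, labels2(10))
  b <- loocv_evaluate("cart", c("SDratio", "CCM"), ft, labels2(10))
  expect_identical(a$scores, b$scores)
  expect_identical(a$auc, b$auc)
})

test_that("logistic and SVM predictions survive affine input rescaling", {
  ft <- make_features(10, 6, 23)
  for (kind in c("logistic", "svm_linear")) {
    base <- loocv_evaluate(kind, "SDratio", ft, labels2(10))
    scaled <- ft
    scaled$SDratio <- 3 * ft$SDratio + 10
    re <- loocv_evaluate(kind, "SDratio", scaled, labels2(10))
    expect_identical(base$predictions, re$predictions)
  }
})

test_that("permuted labels give chance performance", {
  set.seed(24)
  ft <- data.frame(SDratio = rnorm(53))
  set.seed(25)
  res <- replicate(25, {
    l <- sample(rep(c("apnea", "baseline"), c(29, 24)))
    r <- loocv_evaluate("svm_linear", "SDratio", ft, l)
    r2 <- loocv_evaluate("logistic", "SDratio", ft, l)
    c(r$auc, r$accuracy, r2$accuracy)
  })
  expect_lt(abs(mean(res[1, ]) - 0.5), 0.1)
  # accuracy near the 50% chance rate for both classifiers; pooled
  # leave-one-out probabilities are pessimistic under the null, so
  # only an upper excursion would signal leakage
  expect_lt(mean(res[2, ]), 0.65)
  expect_lt(mean(res[3, ]), 0.65)
})

test_that("CART reproduces the exhaustively enumerated best split", {
  # single feature, n = 10; oracle: best Gini split with >= 3 per leaf
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  y <- c("b", "b", "b", "a", "b", "a", "a", "a", "a", "a")
  gini_split <- function(cut) {
    g <- function(lab) {
      p <- mean(lab == "a")
      2 * p * (1 - p)
    }
    left <- y[x <= cut]
    right <- y[x > cut]
    if (length(left) < 3 || length(right) < 3) return(Inf)
    (length(left) * g(left) + length(right) * g(right)) / length(y)
  }
  cuts <- (x[-1] + x[-10]) / 2
  oracle_cut <- cuts[which.min(vapply(cuts, gini_split, numeric(1)))]
  fit <- rpart::rpart(factor(y) ~ x, data.frame(x = x, y = y),
                      method = "class",
                      control = rpart::rpart.control(
                        minsplit = 6, minbucket = 3, cp = 0, xval = 0))
  expect_equal(unname(fit$splits[1, "index"]), oracle_cut)
})

test_that("model search enumerates combos, flags and groups lag ranges", {
  # build a sweep-shaped table with a strong effect at tau 1-2 and
  # none at tau 3
  set.seed(26)
  rows <- list()
  for (tt in 1:3) {
    shift <- if (tt <= 2) 6 else 0
    ft <- make_features(12, shift, 100 + tt)
    rows[[tt]] <- cbind(segment_id = 1:24, label = labels2(12),
                        tau = tt, ft)
  }
  sweep <- do.call(rbind, rows)
  ms <- model_search(sweep, 1:3, classifiers = c("logistic", "cart"))
  expect_equal(nrow(ms$reports), 3 * 5 * 2)
  expect_true(all(ms$reports$flagged ==
                  (ms$reports$auc > 0.8 & ms$reports$accuracy >= 0.8)))
  lg <- ms$best[ms$best$classifier == "logistic" &
                ms$best$inputs == "SDratio", ]
  expect_equal(nrow(lg), 1)
  expect_equal(c(lg$tau_min, lg$tau_max), c(1, 2))
  expect_equal(nrow(model_search(sweep, integer(0))$reports), 0)
})

test_that("default synthetic dataset supports apnea detection at low lags", {
  sweep <- default_sweep()
  ms <- model_search(sweep, c(3, 5, 8, 13))
  expect_gt(nrow(ms$best), 0)
  expect_lte(min(ms$best$tau_min), 13)
  # sanity ordering on a monotone single-feature effect
  cart <- ms$reports[ms$reports$classifier == "cart" &
                     ms$reports$inputs == "SDratio" &
                     ms$reports$tau == 5, ]
  logi <- ms$reports[ms$reports$classifier == "logistic" &
                     ms$reports$inputs == "SDratio" &
                     ms$reports$tau == 5, ]
  expect_gte(cart$accuracy, logi$accuracy - 0.1)
})
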