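# Apnea-vs-baseline hypothesis testing, ROC analysis and pooled
# inter-feature correlations.

# Lilliefors-corrected Kolmogorov-Smirnov normality check; plain
# ks.test is anticonservative when mean/sd are estimated from the data.
is_normalish <- function(x, alpha = 0.05) {
  if (length(x) < 5 || sd(x) == 0) return(FALSE)
  p <- tryCatch(nortest::lillie.test(x)$p.value,
                error = function(e) 0)
  p > alpha
}

#' Normality-gated two-sample comparison
#'
#' When both groups pass the Kolmogorov-Smirnov normality check
#' (Lilliefors correction, alpha = 0.05) a Welch two-sample t-test is
#' used; otherwise a two-sided Mann-Whitney U test. Significance is
#' flagged at the unadjusted 0.05 level and at the Bonferroni-corrected
#' 0.025 level (two feature families compared).
#'
#' @param values_a,values_b numeric vectors, each of length >= 3.
#' @return A one-row data.frame: p_value, test_used ("t" or
#'   "mann_whitney"), significant_unadjusted, significant_bonferroni,
#'   median_a, iqr_a, median_b, iqr_b.
#' @export
#' @examples
#' compare_groups(rnorm(20), rnorm(20, mean = 2))
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 3 || length(values_b) < 3)
    insufficient_data_error("each group needs at least 3 values")
  if (sd(c(values_a, values_b)) == 0) {
    warning("all values identical across both groups; p = 1",
            call. = FALSE)
    p <- 1
    test <- "mann_whitney"
  } else if (is_normalish(values_a) && is_normalish(values_b)) {
    p <- t.test(values_a, values_b)$p.value
    test <- "t"
  } else {
    p <- suppressWarnings(
      wilcox.test(values_a, values_b, exact = FALSE)$p.value)
    test <- "mann_whitney"
  }
  data.frame(p_value = p, test_used = test,
             significant_unadjusted = p < 0.05,
             significant_bonferroni = p < 0.025,
             median_a = median(values_a),
             iqr_a = unname(diff(quantile(values_a, c(0.25, 0.75)))),
             median_b = median(values_b),
             iqr_b = unname(diff(quantile(values_b, c(0.25, 0.75)))))
}

# Rank (Mann-Whitney) AUC of `pos` scores against `neg` scores.
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Single-feature ROC analysis for apnea detection
#'
#' AUC is computed with the rank (Mann-Whitney) formulation and
#' oriented so AUC >= 0.5, recording whether larger or smaller feature
#' values indicate apnea. The operating point is the Youden-optimal
#' threshold (maximizing sensitivity + specificity - 1); sensitivity is
#' the apnea detection rate at that point.
#'
#' @param values numeric feature values, one per segment.
#' @param labels matching labels, `"apnea"` / `"baseline"`.
#' @return A one-row data.frame: auc, sensitivity, specificity,
#'   accuracy, threshold, direction.
#' @export
#' @examples
#' roc_analysis(c(1, 2, 3, 4), c("baseline", "baseline", "apnea", "apnea"))
roc_analysis <- function(values, labels) {
  is_apnea <- labels == "apnea"
  if (!any(is_apnea) || all(is_apnea))
    class_error("both classes must be present")
  ok <- is.finite(values)
  values <- values[ok]
  is_apnea <- is_apnea[ok]
  auc <- rank_auc(values[is_apnea], values[!is_apnea])
  direction <- "greater-is-apnea"
  score <- values
  if (auc < 0.5) {
    auc <- 1 - auc
    direction <- "lesser-is-apnea"
    score <- -values
  }
  v <- sort(unique(score))
  cand <- if (length(v) > 1) (v[-1] + v[-length(v)]) / 2
          else v[1]
  stats_at <- vapply(cand, function(th) {
    pred <- score > th
    sens <- mean(pred[is_apnea])
    spec <- mean(!pred[!is_apnea])
    c(sens, spec)
  }, numeric(2))
  j <- stats_at[1, ] + stats_at[2, ] - 1
  best <- which.max(j)
  sens <- stats_at[1, best]
  spec <- stats_at[2, best]
  acc <- mean((score > cand[best]) == is_apnea)
  th <- if (direction == "greater-is-apnea") cand[best] else -cand[best]
  data.frame(auc = auc, sensitivity = sens, specificity = spec,
             accuracy = acc, threshold = th, direction = direction)
}

#' Per-lag group comparisons and ROC for swept features
#'
#' Convenience over a [feature_sweep()] table: for every feature and
#' lag, runs [compare_groups()] (apnea vs baseline) and
#' [roc_analysis()].
#'
#' @param sweep a [feature_sweep()] data.frame with apnea and baseline
#'   rows.
#' @param features which descriptor columns to test.
#' @return Long data.frame: feature, tau, p_value, test_used,
#'   significant_unadjusted, significant_bonferroni, auc, sensitivity,
#'   specificity, accuracy.
#' @export
compare_by_tau <- function(sweep,
                           features = c("SD1", "SD2", "SDarea",
                                        "SDratio", "R", "CCM")) {
  taus <- sort(unique(sweep$tau))
  rows <- list()
  for (f in features) {
    for (tt in taus) {
      sub <- sweep[sweep$tau == tt & is.finite(sweep[[f]]), ]
      a <- sub[[f]][sub$label == "apnea"]
      b <- sub[[f]][sub$label == "baseline"]
      if (length(a) < 3 || length(b) < 3) next
      cmp <- compare_groups(a, b)
      roc <- roc_analysis(sub[[f]], sub$label)
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, tau = tt, p_value = cmp$p_value,
        test_used = cmp$test_used,
        significant_unadjusted = cmp$significant_unadjusted,
        significant_bonferroni = cmp$significant_bonferroni,
        auc = roc$auc, sensitivity = roc$sensitivity,
        specificity = roc$specificity, accuracy = roc$accuracy)
    }
  }
  do.call(rbind, rows)
}

#' Pooled pairwise correlations among SDratio, R and CCM
#'
#' Pearson correlations over all segments and all lags pooled together
#' (pairwise-complete observations).
#'
#' @param feature_table a [feature_sweep()] data.frame.
#' @param features columns to correlate.
#' @return A list: `r` (correlation matrix), `p` (p-value matrix), `n`
#'   (pairwise counts), `n_rows` (rows in the pooled table).
#' @export
feature_correlations <- function(feature_table,
                                 features = c("SDratio", "R", "CCM")) {
  X <- feature_table[, features, drop = FALSE]
  if (sum(complete.cases(X)) < 3)
    insufficient_data_error("need at least 3 complete rows")
  k <- length(features)
  r <- p <- n <- matrix(NA_real_, k, k,
                        dimnames = list(features, features))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ok <- is.finite(X[[i]]) & is.finite(X[[j]])
      n[i, j] <- sum(ok)
      if (i == j) {
        r[i, j] <- 1
        p[i, j] <- 0
      } else if (n[i, j] >= 3) {
        ct <- cor.test(X[[i]][ok], X[[j]][ok])
        r[i, j] <- unname(ct$estimate)
        p[i, j] <- ct$p.value
      }
    }
  }
  list(r = r, p = p, n = n, n_rows = nrow(X))
}
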