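# Relief feature weighting and leave-one-out validated apnea/baseline
# classification (logistic regression, Gaussian naive Bayes, linear
# SVM, CART).

#' Candidate input combinations
#'
#' All non-empty subsets of \{SDratio, R, CCM\} except those containing
#' both SDratio and R, which are nearly collinear and are excluded from
#' the model search.
#'
#' @return List of character vectors (exactly five combinations).
#' @export
input_combos <- function() {
  list("SDratio", "R", "CCM",
       c("SDratio", "CCM"), c("R", "CCM"))
}

#' Relief feature weights
#'
#' Classic Relief: features are min-max scaled to \[0, 1\]; for every
#' sample its nearest hit (same class) and nearest miss (other class)
#' are found by Euclidean distance and each feature weight accumulates
#' `|x_f - miss_f| - |x_f - hit_f|`, averaged over samples. Informative
#' features receive positive weights, irrelevant ones weights near 0.
#'
#' @param feature_matrix numeric matrix or data.frame (samples x
#'   features), all finite.
#' @param labels class labels, two classes, >= 2 samples each.
#' @return Named numeric vector of weights.
#' @export
relief_weights <- function(feature_matrix, labels) {
  X <- as.matrix(feature_matrix)
  if (!all(is.finite(X))) config_error("features must be finite")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2 || min(table(labels)) < 2)
    class_error("need at least 2 samples in each of 2 classes")
  rng <- apply(X, 2, function(col) diff(range(col)))
  Xs <- sweep(X, 2, apply(X, 2, min))
  nz <- rng > 0
  Xs[, nz] <- sweep(Xs[, nz, drop = FALSE], 2, rng[nz], "/")
  n <- nrow(Xs)
  D <- as.matrix(dist(Xs))
  diag(D) <- Inf
  w <- numeric(ncol(Xs))
  for (i in seq_len(n)) {
    same <- labels == labels[i]
    same[i] <- FALSE
    hit <- which(same)[which.min(D[i, same])]
    miss <- which(!same)[which.min(D[i, !same])]
    w <- w + abs(Xs[i, ] - Xs[miss, ]) - abs(Xs[i, ] - Xs[hit, ])
  }
  setNames(w / n, colnames(X))
}

# Fit on train, return held-out apnea score (probability, or decision
# value for the SVM) and predicted class for one fold.
fit_score <- function(kind, train, test) {
  train$y <- factor(train$y, levels = c("baseline", "apnea"))
  switch(kind,
    logistic = {
      fit <- suppressWarnings(glm(y ~ ., data = train,
                                  family = binomial()))
      p <- suppressWarnings(
        as.numeric(predict(fit, test, type = "response")))
      list(score = p, pred = ifelse(p > 0.5, "apnea", "baseline"))
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(y ~ ., data = train)
      p <- predict(fit, test, type = "raw")[, "apnea"]
      list(score = as.numeric(p),
           pred = ifelse(p > 0.5, "apnea", "baseline"))
    },
    svm_linear = {
      fit <- e1071::svm(y ~ ., data = train, kernel = "linear",
                        cost = 1, probability = FALSE)
      pr <- predict(fit, test, decision.values = TRUE)
      dv <- as.numeric(attr(pr, "decision.values"))
      # decision values are positive toward the class named first in
      # the "A/B" column label; orient so larger means apnea
      if (grepl("^baseline/", colnames(attr(pr, "decision.values"))[1]))
        dv <- -dv
      list(score = dv, pred = as.character(pr))
    },
    cart = {
      fit <- rpart::rpart(y ~ ., data = train, method = "class",
                          parms = list(split = "gini"),
                          control = rpart::rpart.control(
                            minsplit = 6, minbucket = 3, cp = 0,
                            xval = 0))
      p <- predict(fit, test, type = "prob")[, "apnea"]
      list(score = as.numeric(p),
           pred = ifelse(p > 0.5, "apnea", "baseline"))
    },
    config_error(sprintf("unknown classifier kind '%s'", kind)))
}

#' Leave-one-out evaluation of one classifier on one input combination
#'
#' Each segment is held out once; the model is trained on the rest and
#' scores the held-out segment (class probability, or decision value
#' for the SVM). Accuracy is the fraction of correct thresholded
#' predictions over folds; AUC is the rank AUC of the pooled held-out
#' scores. All four classifiers are deterministic given the data, so
#' repeated runs give identical reports.
#'
#' @param classifier_kind one of `"logistic"`, `"naive_bayes"`,
#'   `"svm_linear"`, `"cart"`.
#' @param combo character vector of feature columns (an
#'   [input_combos()] element).
#' @param feature_table data.frame holding the `combo` columns, one row
#'   per segment.
#' @param labels `"apnea"` / `"baseline"` per segment.
#' @return A list of class `classifier_report`: classifier, combo, auc,
#'   accuracy, scores (held-out), predictions, labels.
#' @export
loocv_evaluate <- function(classifier_kind, combo, feature_table,
                           labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2 || min(table(labels)) < 2)
    class_error("need at least 2 samples per class")
  if (any(c("SDratio", "R") %in% combo) &&
      all(c("SDratio", "R") %in% combo))
    config_error("combinations with both SDratio and R are excluded")
  df <- feature_table[, combo, drop = FALSE]
  ok <- complete.cases(df)
  df <- df[ok, , drop = FALSE]
  labels <- labels[ok]
  n <- nrow(df)
  scores <- rep(NA_real_, n)
  preds <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    train <- cbind(df[-i, , drop = FALSE], y = labels[-i])
    if (length(unique(labels[-i])) < 2) {
      warning(sprintf("fold %d skipped: single-class training set", i),
              call. = FALSE)
      next
    }
    r <- fit_score(classifier_kind, train, df[i, , drop = FALSE])
    scores[i] <- r$score
    preds[i] <- r$pred
  }
  done <- !is.na(scores)
  auc <- rank_auc(scores[done & labels == "apnea"],
                  scores[done & labels == "baseline"])
  structure(list(classifier = classifier_kind, combo = combo,
                 auc = auc,
                 accuracy = mean(preds[done] == labels[done]),
                 scores = scores, predictions = preds,
                 labels = labels),
            class = "classifier_report")
}

#' Search classifiers x input combinations x lags
#'
#' Evaluates every classifier on every admissible input combination at
#' every lag with leave-one-out validation, flags reports with
#' AUC > 0.8 and accuracy >= 0.80, and groups contiguous flagged lag
#' ranges per classifier/combination.
#'
#' @param sweep a [feature_sweep()] table covering the requested lags.
#' @param tau_values lags to evaluate.
#' @param classifiers classifier kinds to include.
#' @return A list: `reports` (data.frame: classifier, inputs, tau, auc,
#'   accuracy, flagged) and `best` (data.frame of contiguous flagged
#'   ranges: classifier, inputs, tau_min, tau_max, auc_mean, auc_sd,
#'   acc_mean, acc_sd).
#' @export
model_search <- function(sweep, tau_values,
                         classifiers = c("logistic", "naive_bayes",
                                         "svm_linear", "cart")) {
  rows <- list()
  for (tt in tau_values) {
    sub <- sweep[sweep$tau == tt, ]
    feats <- sub[, c("SDratio", "R", "CCM")]
    for (combo in input_combos()) {
      for (kind in classifiers) {
        rep_ <- loocv_evaluate(kind, combo, feats, sub$label)
        rows[[length(rows) + 1]] <- data.frame(
          classifier = kind,
          inputs = paste(combo, collapse = "+"),
          tau = tt, auc = rep_$auc, accuracy = rep_$accuracy)
      }
    }
  }
  reports <- do.call(rbind, rows)
  if (is.null(reports))
    return(list(reports = data.frame(), best = data.frame()))
  reports$flagged <- reports$auc > 0.8 & reports$accuracy >= 0.80

  best <- list()
  fl <- reports[reports$flagged, ]
  if (nrow(fl) > 0) {
    for (key in unique(paste(fl$classifier, fl$inputs, sep = "|"))) {
      sub <- fl[paste(fl$classifier, fl$inputs, sep = "|") == key, ]
      sub <- sub[order(sub$tau), ]
      grp <- cumsum(c(1, diff(sub$tau) != 1))
      for (g in unique(grp)) {
        s <- sub[grp == g, ]
        best[[length(best) + 1]] <- data.frame(
          classifier = s$classifier[1], inputs = s$inputs[1],
          tau_min = min(s$tau), tau_max = max(s$tau),
          auc_mean = mean(s$auc),
          auc_sd = if (nrow(s) > 1) sd(s$auc) else 0,
          acc_mean = mean(s$accuracy),
          acc_sd = if (nrow(s) > 1) sd(s$accuracy) else 0)
      }
    }
  }
  list(reports = reports,
       best = if (length(best)) do.call(rbind, best) else data.frame())
}
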