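#' Classifier specification
#'
#' The three classifiers of the analysis: a support vector machine
#' (`e1071::svm`; linear kernel, cost 1 by default — a sensible default for
#' ~11 features and ~67 samples; RBF configurable), logistic regression
#' (`stats::glm`, binomial, the standard sigmoid model fit by maximum
#' likelihood), and a CART decision tree (`rpart` with the Gini split
#' criterion). The positive class is `"HA"` (high altitude).
#'
#' @param kind `"SVM"`, `"LR"` or `"DT"`.
#' @param kernel,cost SVM hyperparameters.
#' @param minsplit,minbucket,maxdepth,cp Decision-tree controls (`rpart`);
#'   `minsplit`/`minbucket` default low because training folds are small.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("SVM", "LR", "DT"), kernel = "linear",
                            cost = 1, minsplit = 5, minbucket = 2,
                            maxdepth = 30, cp = 0.01) {
  kind <- match.arg(kind)
  structure(list(kind = kind, kernel = kernel, cost = cost,
                 minsplit = minsplit, minbucket = minbucket,
                 maxdepth = maxdepth, cp = cp, positive_class = "HA"),
            class = "classifier_spec")
}

#' Default classifier set
#'
#' @return Named list of the SVM, LR and DT [classifier_spec()]s.
#' @export
default_classifier_specs <- function() {
  list(SVM = classifier_spec("SVM"),
       LR = classifier_spec("LR"),
       DT = classifier_spec("DT"))
}

# Fit on (x, y) and score new points: returns function(newx) -> score where
# higher means more HA-like. Deterministic.
fit_scorer <- function(x, y, spec) {
  df <- as.data.frame(x)
  switch(spec$kind,
    SVM = {
      yf <- factor(y, levels = c("HA", "LA"))
      fit <- e1071::svm(x, yf, kernel = spec$kernel, cost = spec$cost,
                        scale = FALSE)
      function(newx) {
        pr <- stats::predict(fit, newx, decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        if (grepl("^HA/", colnames(dv)[1])) as.numeric(dv) else -as.numeric(dv)
      }
    },
    LR = {
      df$.y <- as.integer(y == "HA")
      fit <- suppressWarnings(
        stats::glm(.y ~ ., data = df, family = stats::binomial()))
      function(newx) {
        suppressWarnings(
          as.numeric(stats::predict(fit, newdata = as.data.frame(newx),
                                    type = "link")))
      }
    },
    DT = {
      df$.y <- factor(y, levels = c("HA", "LA"))
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          parms = list(split = "gini"),
                          control = rpart::rpart.control(
                            minsplit = spec$minsplit,
                            minbucket = spec$minbucket,
                            maxdepth = spec$maxdepth, cp = spec$cp,
                            xval = 0))
      function(newx) {
        pr <- stats::predict(fit, newdata = as.data.frame(newx), type = "prob")
        as.numeric(pr[, "HA"]) - 0.5
      }
    })
}

#' Leave-one-out cross-validated predictions
#'
#' Trains the classifier n times, each time holding out one sample, and
#' predicts the held-out sample. Scores are oriented so that higher means
#' more HA-like; the predicted label is HA iff the score is positive
#' (probability above one half for the tree).
#'
#' @param x Numeric matrix/data frame of features (rows = samples).
#' @param labels Character/factor of `"HA"` / `"LA"`.
#' @param spec A [classifier_spec()].
#' @param select_in_fold Optional function `(x_train, labels_train) ->
#'   feature names`; when supplied, normalization-agnostic feature selection
#'   is re-run inside every training fold (leakage-safe mode).
#' @return `data.frame` with columns `observed`, `predicted`, `score`.
#' @export
loocv_predict <- function(x, labels, spec, select_in_fold = NULL) {
  m <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(m)
  if (any(table(labels) < 2))
    stop("need at least 2 samples per class for leave-one-out training folds")
  score <- numeric(n)
  for (i in seq_len(n)) {
    tr_x <- m[-i, , drop = FALSE]
    tr_y <- labels[-i]
    if (length(unique(tr_y)) < 2)
      stop("a training fold contains a single class")
    te_x <- m[i, , drop = FALSE]
    if (!is.null(select_in_fold)) {
      keep <- select_in_fold(tr_x, tr_y)
      tr_x <- tr_x[, keep, drop = FALSE]
      te_x <- te_x[, keep, drop = FALSE]
    }
    score[i] <- fit_scorer(tr_x, tr_y, spec)(te_x)
  }
  data.frame(observed = labels,
             predicted = ifelse(score > 0, "HA", "LA"),
             score = score, stringsAsFactors = FALSE)
}

#' Confusion-matrix counts
#'
#' Tabulates TP/FN/FP/TN with HA as the positive class.
#'
#' @param observed,predicted Character vectors of `"HA"` / `"LA"`.
#' @return Named list `TP`, `FN`, `FP`, `TN`.
#' @export
confusion_counts <- function(observed, predicted) {
  list(TP = sum(observed == "HA" & predicted == "HA"),
       FN = sum(observed == "HA" & predicted == "LA"),
       FP = sum(observed == "LA" & predicted == "HA"),
       TN = sum(observed == "LA" & predicted == "LA"))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/n`, sensitivity (recall) `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and the F1 score
#' `2 * precision * recall / (precision + recall)`. A metric with a zero
#' denominator is returned as `NA`.
#'
#' @param cm Named list with `TP`, `FN`, `FP`, `TN` (see
#'   [confusion_counts()]).
#' @return Named list `accuracy`, `precision`, `sensitivity`, `specificity`,
#'   `f1`.
#' @export
confusion_metrics <- function(cm) {
  n <- cm$TP + cm$FN + cm$FP + cm$TN
  if (n == 0) stop("empty confusion matrix")
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  precision <- safe_div(cm$TP, cm$TP + cm$FP)
  recall <- safe_div(cm$TP, cm$TP + cm$FN)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(accuracy = (cm$TP + cm$TN) / n,
       precision = precision,
       sensitivity = recall,
       specificity = safe_div(cm$TN, cm$TN + cm$FP),
       f1 = f1)
}

#' Wald confidence interval for a proportion
#'
#' Normal-approximation interval `p +/- z * sqrt(p(1-p)/n)`, clipped to
#' \[0, 1\]. Note that two-decimal-rounded accuracies reproduce intervals
#' printed alongside rounded percentages (e.g. 92.54% on n = 67 gives
#' (86.25%, 98.83%)); the raw count 62/67 gives a lower bound of 86.24%.
#'
#' @param p Proportion in \[0, 1\].
#' @param n Number of trials (> 0).
#' @param level Confidence level.
#' @return Named numeric `c(lower, upper)`.
#' @export
wald_ci <- function(p, n, level = 0.95) {
  stopifnot(n > 0, p >= 0, p <= 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(lower = max(0, p - half), upper = min(1, p + half))
}

#' Wald confidence interval for an observed accuracy
#'
#' @param n_correct Number of correct predictions.
#' @param n Total predictions.
#' @param level Confidence level.
#' @return Named numeric `c(lower, upper)`.
#' @export
accuracy_ci <- function(n_correct, n, level = 0.95) {
  stopifnot(n > 0, n_correct >= 0, n_correct <= n)
  wald_ci(n_correct / n, n, level)
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds and reports (FPR, TPR) points; the AUC is the
#' Mann-Whitney probability that a random HA sample scores above a random LA
#' sample, with ties counted half (midranks).
#'
#' @param scores Numeric scores, higher = more HA-like.
#' @param labels `"HA"` / `"LA"` labels.
#' @return List with `curve` (`data.frame` `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  pos <- labels == "HA"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)                      # midranks
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(scores >= t & !pos) / n_neg, 0),
    tpr = vapply(thr, function(t) sum(scores >= t & pos) / n_pos, 0))
  list(curve = curve, auc = auc)
}

#' Evaluate all classifiers over all task periods
#'
#' For each period's feature table: impute missing values by column medians,
#' min-max normalize, rank features by ReliefF and GainRatio, keep the
#' intersection of the two top-`k` lists, then evaluate every classifier by
#' leave-one-out cross-validation and report the confusion matrix, accuracy
#' (with Wald CI), F1, sensitivity, specificity, ROC curve and AUC.
#'
#' By default selection is performed once on the full table before
#' cross-validation, mirroring a sequential analysis description; note this
#' leaks label information into the folds and optimistically biases the
#' metrics — `selection_scope = "per_fold"` re-selects inside every training
#' fold and is the leakage-safe mode recommended for real inference.
#'
#' @param tables Named list of per-period feature data frames (rows =
#'   participants, 36 feature columns).
#' @param labels `"HA"` / `"LA"` vector (same rows in every table).
#' @param specs Named list of [classifier_spec()]s.
#' @param k_top Depth of each ranking's top list (default 18).
#' @param relieff_k ReliefF neighbor count; clamped to min class size - 1.
#' @param selection_scope `"full"` or `"per_fold"`.
#' @param ci_level Confidence level of the accuracy interval.
#' @return Object of class `gsat_report`: nested list
#'   `report$cells[[period]][[classifier]]` with `confusion`, `metrics`,
#'   `accuracy_ci`, `roc` (curve + AUC); plus `selected[[period]]`,
#'   `rankings[[period]]`, `labels`. `as.data.frame()` flattens the metrics.
#' @export
evaluate_all <- function(tables, labels, specs = default_classifier_specs(),
                         k_top = 18, relieff_k = 10,
                         selection_scope = c("full", "per_fold"),
                         ci_level = 0.95) {
  selection_scope <- match.arg(selection_scope)
  labels <- as.character(labels)
  k_eff <- min(relieff_k, min(table(labels)) - 1)
  select_fun <- function(x, y) {
    xn <- minmax_normalize(impute_median(x))
    intersect_top_k(relieff_rank(xn, y, k = min(k_eff, min(table(y)) - 1)),
                    gainratio_rank(xn, y), k = k_top)
  }
  out <- list(cells = list(), selected = list(), rankings = list(),
              labels = labels, selection_scope = selection_scope)
  for (period in names(tables)) {
    x <- tables[[period]]
    stopifnot(nrow(x) == length(labels))
    xn <- minmax_normalize(impute_median(x))
    r1 <- relieff_rank(xn, labels, k = k_eff)
    r2 <- gainratio_rank(xn, labels)
    sel <- intersect_top_k(r1, r2, k = k_top)
    out$rankings[[period]] <- list(relieff = r1, gainratio = r2)
    out$selected[[period]] <- sel
    cells <- list()
    for (cn in names(specs)) {
      preds <- if (selection_scope == "full") {
        loocv_predict(xn[, sel, drop = FALSE], labels, specs[[cn]])
      } else {
        loocv_predict(xn, labels, specs[[cn]], select_in_fold = select_fun)
      }
      cm <- confusion_counts(preds$observed, preds$predicted)
      met <- confusion_metrics(cm)
      roc <- roc_auc(preds$score, preds$observed)
      cells[[cn]] <- list(confusion = cm, metrics = met,
                          accuracy_ci = accuracy_ci(cm$TP + cm$TN,
                                                    length(labels), ci_level),
                          roc = roc, predictions = preds)
    }
    out$cells[[period]] <- cells
  }
  class(out) <- "gsat_report"
  out
}

#' Flatten an evaluation report to a data frame
#'
#' @param x A `gsat_report`.
#' @param ... Unused.
#' @return `data.frame` with one row per classifier x period and columns for
#'   every metric, CI bound, AUC and confusion count.
#' @export
as.data.frame.gsat_report <- function(x, ...) {
  rows <- list()
  for (period in names(x$cells)) {
    for (cn in names(x$cells[[period]])) {
      cell <- x$cells[[period]][[cn]]
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = cn, period = period,
        accuracy = cell$metrics$accuracy,
        ci_lower = cell$accuracy_ci[["lower"]],
        ci_upper = cell$accuracy_ci[["upper"]],
        f1 = cell$metrics$f1,
        sensitivity = cell$metrics$sensitivity,
        specificity = cell$metrics$specificity,
        auc = cell$roc$auc,
        TP = cell$confusion$TP, FN = cell$confusion$FN,
        FP = cell$confusion$FP, TN = cell$confusion$TN,
        n_selected = length(x$selected[[period]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
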