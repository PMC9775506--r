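sep_toy <- function(n_per = 6, gap = 4, seed = 13) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2, 0, 0.3), ncol = 2),
             matrix(rnorm(n_per * 2, gap, 0.3), ncol = 2))
  colnames(x) <- c("u", "v")
  list(x = x, y = rep(c("HA", "LA"), each = n_per))
}

test_that("LOOCV yields one held-out prediction per sample", {
  toy <- sep_toy()
  for (spec in default_classifier_specs()) {
    p <- loocv_predict(toy$x, toy$y, spec)
    expect_equal(nrow(p), 12)
    expect_equal(p$observed, toy$y)
  }
})

test_that("a linearly separable set is classified perfectly by the linear SVM", {
  toy <- sep_toy()
  p <- loocv_predict(toy$x, toy$y, classifier_spec("SVM"))
  expect_equal(p$predicted, toy$y)
  # fold-by-fold enumeration oracle: each fold alone is separable, so a
  # direct per-fold fit must agree with the pipeline's predictions
  for (i in seq_len(nrow(toy$x))) {
    fit <- e1071::svm(toy$x[-i, ], factor(toy$y[-i], c("HA", "LA")),
                      kernel = "linear", cost = 1, scale = FALSE)
    expect_equal(as.character(predict(fit, toy$x[i, , drop = FALSE])),
                 p$predicted[i])
  }
})

test_that("degenerate training folds are rejected", {
  x <- cbind(f = c(0, 1))
  expect_error(loocv_predict(x, c("HA", "LA"), classifier_spec("SVM")),
               "at least 2 samples per class")
})

test_that("LOOCV is deterministic across repeated runs", {
  toy <- sep_toy(gap = 1)
  for (spec in default_classifier_specs()) {
    p1 <- loocv_predict(toy$x, toy$y, spec)
    p2 <- loocv_predict(toy$x, toy$y, spec)
    expect_identical(p1, p2)
  }
})

test_that("confusion metrics reproduce the worked examples", {
  m <- confusion_metrics(list(TP = 32, FN = 3, FP = 2, TN = 30))
  expect_equal(round(m$accuracy, 4), 0.9254)
  expect_equal(round(m$sensitivity, 4), 0.9143)
  expect_equal(round(m$specificity, 4), 0.9375)
  expect_equal(round(m$f1, 2), 0.93)
  m2 <- confusion_metrics(list(TP = 32, FN = 3, FP = 0, TN = 32))
  expect_equal(round(m2$accuracy, 4), 0.9552)
  expect_equal(round(m2$f1, 4), 0.9552)
  m3 <- confusion_metrics(list(TP = 10, FN = 0, FP = 0, TN = 12))
  expect_equal(unlist(m3), c(accuracy = 1, precision = 1, sensitivity = 1,
                             specificity = 1, f1 = 1))
  # undefined metric flags
  m4 <- confusion_metrics(list(TP = 0, FN = 5, FP = 0, TN = 5))
  expect_true(is.na(m4$precision))
})

test_that("confusion counts conserve totals and class sizes", {
  set.seed(2)
  obs <- sample(c("HA", "LA"), 30, replace = TRUE, prob = c(0.6, 0.4))
  pred <- sample(c("HA", "LA"), 30, replace = TRUE)
  cm <- confusion_counts(obs, pred)
  expect_equal(cm$TP + cm$FN + cm$FP + cm$TN, 30)
  expect_equal(cm$TP + cm$FN, sum(obs == "HA"))
  expect_equal(cm$TN + cm$FP, sum(obs == "LA"))
  m <- confusion_metrics(cm)
  n_pos <- sum(obs == "HA"); n_neg <- sum(obs == "LA")
  expect_equal(m$accuracy,
               (m$sensitivity * n_pos + m$specificity * n_neg) / 30)
})

test_that("the Wald interval reproduces printed CIs and clips at the edges", {
  ci <- wald_ci(0.7015, 67)
  expect_equal(round(100 * unname(ci), 2), c(59.19, 81.11))
  ci2 <- accuracy_ci(47, 67)
  expect_equal(round(100 * unname(ci2), 2), c(59.19, 81.11))
  ci3 <- accuracy_ci(67, 67)
  expect_equal(unname(ci3), c(1, 1))
  expect_equal(unname(wald_ci(0, 10)), c(0, 0))
})

test_that("ROC/AUC follow the Mann-Whitney midrank convention", {
  y <- rep(c("HA", "LA"), each = 4)
  expect_equal(roc_auc(c(4, 3, 5, 6, 0, 1, 2, -1), y)$auc, 1.0)
  expect_equal(roc_auc(c(0, 1, 2, -1, 4, 3, 5, 6), y)$auc, 0.0)
  expect_equal(roc_auc(rep(2, 8), y)$auc, 0.5)
  expect_error(roc_auc(1:4, rep("HA", 4)), "both classes")
  # curve endpoints span (0,0) to (1,1)
  set.seed(6)
  r <- roc_auc(rnorm(20), rep(c("HA", "LA"), 10))
  expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
  expect_equal(utils::tail(r$curve$fpr, 1), 1)
  expect_equal(utils::tail(r$curve$tpr, 1), 1)
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  for (rep in 1:4) {
    y <- rep(c("HA", "LA"), each = 15)
    s <- rnorm(30) + (y == "HA") * runif(1, 0, 2)
    s <- round(s, 1)                 # force ties
    ours <- roc_auc(s, y)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = s, levels = c("LA", "HA"),
      direction = "<", quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("evaluate_all produces a full classifier-by-period grid with consistent internals", {
  set.seed(55)
  n <- 10
  mk_tab <- function() {
    as.data.frame(matrix(runif(2 * n * 36), 2 * n, 36,
                         dimnames = list(NULL, feature_names())))
  }
  tabs <- list(a1 = mk_tab(), a2 = mk_tab(), a3 = mk_tab())
  labels <- rep(c("HA", "LA"), each = n)
  # make a few features informative so the intersection is non-empty
  for (pd in names(tabs)) {
    tabs[[pd]]$go_latency <- c(rnorm(n, 0), rnorm(n, 3))
    tabs[[pd]]$nogo_mean <- c(rnorm(n, 0), rnorm(n, 3))
    tabs[[pd]]$go_area <- c(rnorm(n, 0), rnorm(n, 2))
  }
  rep_ <- evaluate_all(tabs, labels, relieff_k = 5)
  df <- as.data.frame(rep_)
  expect_equal(nrow(df), 9)
  expect_setequal(unique(df$period), c("a1", "a2", "a3"))
  expect_setequal(unique(df$classifier), c("SVM", "LR", "DT"))
  expect_equal(df$accuracy, (df$TP + df$TN) / (2 * n))
  expect_true(all(df$TP + df$FN == n & df$TN + df$FP == n))
  expect_true(all(df$auc >= 0 & df$auc <= 1))
  expect_true(all(df$ci_lower >= 0 & df$ci_upper <= 1))
  # determinism of the whole report
  rep2 <- evaluate_all(tabs, labels, relieff_k = 5)
  expect_identical(as.data.frame(rep2), df)
})

test_that("per-fold selection mode runs and reports the same structure", {
  set.seed(77)
  n <- 8
  tab <- as.data.frame(matrix(runif(2 * n * 36), 2 * n, 36,
                              dimnames = list(NULL, feature_names())))
  tab$go_latency <- c(rnorm(n, 0, 0.5), rnorm(n, 3, 0.5))
  tab$nogo_latency <- c(rnorm(n, 0, 0.5), rnorm(n, 3, 0.5))
  labels <- rep(c("HA", "LA"), each = n)
  rep_ <- evaluate_all(list(a1 = tab), labels, relieff_k = 3,
                       selection_scope = "per_fold")
  df <- as.data.frame(rep_)
  expect_equal(nrow(df), 3)
  expect_true(all(df$TP + df$FN + df$FP + df$TN == 2 * n))
})
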