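# Metric battery: worked examples, brute-force oracle, identities.

# independent brute-force oracle: recompute every metric from the enumerated
# label vectors, without touching the confusion matrix path
oracle_metrics <- function(yt, yp) {
  tp <- sum(yt == 1 & yp == 1); tn <- sum(yt == 0 & yp == 0)
  fp <- sum(yt == 0 & yp == 1); fn <- sum(yt == 1 & yp == 0)
  n <- length(yt)
  div <- function(a, b) if (b == 0) 0 else a / b
  prec <- c(div(tn, tn + fn), div(tp, tp + fp))
  rec <- c(div(tn, tn + fp), div(tp, tp + fn))
  po <- mean(yt == yp)
  pe <- (mean(yt == 1) * mean(yp == 1)) + (mean(yt == 0) * mean(yp == 0))
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(accuracy = po,
       precision = prec, recall = rec,
       balanced_accuracy = mean(rec),
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den,
       kappa = if (pe == 1) 0 else (po - pe) / (1 - pe),
       jaccard = div(tp, tp + fp + fn),
       youden = rec[2] + rec[1] - 1,
       g_mean = sqrt(rec[1] * rec[2]))
}

test_that("confusion matrices count labels correctly", {
  expect_equal(unclass(confusion_from_predictions(c(0, 1), c(0, 1))),
               matrix(c(1L, 0L, 0L, 1L), 2), ignore_attr = TRUE)
  cm <- confusion_from_predictions(c(0, 0, 1), c(1, 0, 1))
  expect_equal(as.integer(cm), c(1L, 0L, 1L, 1L))  # column-major [a,p]
  expect_error(confusion_from_predictions(integer(0), integer(0)),
               "non-empty")
  expect_error(confusion_from_predictions(c(0, 2), c(0, 1)), "\\{0, 1\\}")
})

test_that("a printed classification report reconstructs its matrix", {
  cm <- reconstruct_confusion_from_report(50, 0.96, 52, 1.00)
  expect_equal(as.integer(cm), c(48L, 0L, 2L, 52L))
  # implied precisions cross-check against the printed report
  expect_equal(48 / (48 + 0), 1.00)
  expect_equal(round(52 / (52 + 2), 2), 0.96)
  perfect <- reconstruct_confusion_from_report(10, 1, 10, 1)
  expect_equal(as.integer(perfect), c(10L, 0L, 0L, 10L))
  expect_error(reconstruct_confusion_from_report(10, 0.95, 10, 1),
               "not integral")
})

test_that("the battery reproduces the reference test-set report", {
  cm <- reconstruct_confusion_from_report(50, 0.96, 52, 1.00)
  m <- compute_metrics(cm)
  r <- format_report(m, digits = 2)
  expect_equal(r[["accuracy"]], 0.98)
  expect_equal(r[["mcc"]], 0.96)
  expect_equal(r[["balanced_accuracy"]], 0.98)
  expect_equal(r[["youden_j"]], 0.96)
  expect_equal(r[["specificity"]], 0.96)
  expect_equal(m$sensitivity, 1.0)
  expect_equal(r[["macro_f1"]], 0.98)
  expect_equal(m$accuracy, 100 / 102)
  # G-mean: the oracle value rounds to 0.98, not 0.97 -- kept at full precision
  expect_equal(m$g_mean, sqrt(0.96), tolerance = 1e-12)
  expect_equal(round(m$g_mean, 2), 0.98)
})

test_that("a perfect matrix maximizes every rate metric", {
  m <- compute_metrics(matrix(c(50, 0, 0, 52), 2))
  for (nm in c("accuracy", "macro_f1", "balanced_accuracy", "mcc",
               "cohens_kappa", "jaccard", "sensitivity", "specificity",
               "g_mean"))
    expect_equal(m[[nm]], 1, info = nm)
  expect_equal(m$youden_j, 1)
})

test_that("every metric agrees with the brute-force oracle on random samples", {
  set.seed(202)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    yt <- sample(0:1, n, replace = TRUE)
    yp <- sample(0:1, n, replace = TRUE)
    cm <- confusion_from_predictions(yt, yp)
    m <- suppressWarnings(compute_metrics(cm))
    o <- oracle_metrics(yt, yp)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$per_class$precision, o$precision)
    expect_equal(m$per_class$recall, o$recall)
    expect_equal(m$balanced_accuracy, o$balanced_accuracy)
    expect_equal(m$mcc, o$mcc)
    expect_equal(m$cohens_kappa, o$kappa)
    expect_equal(m$jaccard, o$jaccard)
    expect_equal(m$youden_j, o$youden)
    expect_equal(m$g_mean, o$g_mean)
    # identities: weighted recall is accuracy; g-mean squared factorizes
    expect_equal(m$weighted_recall, m$accuracy)
    expect_equal(m$g_mean^2, m$sensitivity * m$specificity)
  }
})

test_that("class-specific metrics swap correctly under class relabeling", {
  set.seed(33)
  yt <- sample(0:1, 60, replace = TRUE)
  yp <- sample(0:1, 60, replace = TRUE)
  m <- compute_metrics(confusion_from_predictions(yt, yp))
  ms <- compute_metrics(confusion_from_predictions(1 - yt, 1 - yp))
  expect_equal(ms$sensitivity, m$specificity)
  expect_equal(ms$specificity, m$sensitivity)
  expect_equal(ms$accuracy, m$accuracy)
  expect_equal(abs(ms$mcc), abs(m$mcc))
  expect_equal(ms$youden_j, m$youden_j)   # symmetric in the two recalls
})

test_that("score-based metrics need scores and follow closed forms", {
  cm <- matrix(c(5, 5, 5, 5), 2)
  m <- compute_metrics(cm)
  expect_true(is.na(m$log_loss) && is.na(m$brier) && is.na(m$roc_auc))
  yt <- rep(0:1, 10)
  ms <- compute_metrics(confusion_from_predictions(yt, yt),
                        scores = rep(0.5, 20), y_true = yt)
  expect_equal(ms$log_loss, log(2))       # uniform probabilities
  expect_equal(ms$brier, 0.25)
  expect_error(compute_metrics(cm, scores = rep(0.5, 20)), "y_true")
})

test_that("zero-denominator conventions return 0 with a warning", {
  cm <- matrix(c(0, 0, 3, 7), 2)          # nothing predicted negative
  w <- capture_warnings(m <- compute_metrics(cm))
  expect_true(any(grepl("zero denominator", w)))
  expect_equal(m$per_class$precision[1], 0)
  cm1 <- matrix(c(10, 0, 0, 0), 2)        # one-class marginals
  w1 <- capture_warnings(m1 <- compute_metrics(cm1))
  expect_true(any(grepl("MCC", w1)))
  expect_equal(m1$mcc, 0)
})

test_that("ROC curves hit the standard landmarks", {
  yt <- c(0, 0, 0, 1, 1, 1)
  perfect <- roc_curve(c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9), yt)
  expect_equal(perfect$auc, 1)
  expect_equal(roc_curve(rep(0.4, 6), yt)$auc, 0.5)
  set.seed(44)
  s <- runif(30); y <- sample(0:1, 30, replace = TRUE)
  y[1:2] <- 0:1
  r <- roc_curve(s, y)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))  # monotone
  expect_equal(roc_curve(-s, y)$auc, 1 - r$auc)                # reversal
  expect_gte(r$auc, 0); expect_lte(r$auc, 1)
  expect_error(roc_curve(s, rep(1, 30)), "one positive and one negative")
})

test_that("ROC AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(55)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    y <- sample(0:1, n, replace = TRUE); y[1:2] <- 0:1
    s <- runif(n) + 0.5 * y
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_curve(s, y)$auc, ref, tolerance = 1e-10)
  }
})
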