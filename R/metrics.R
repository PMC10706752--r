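# Binary classification metric battery.
#
# Class convention throughout: 0 = non-recurring (negative), 1 = recurring
# (positive). A confusion matrix is stored as counts[actual, predicted] with
# classes in that order, so sensitivity is the recall of class 1 and
# specificity the recall of class 0.

#' Build a 2x2 confusion matrix from labels
#'
#' @param y_true,y_pred Equal-length integer vectors over \{0, 1\}.
#' @return Integer 2x2 matrix of class `confusion_2x2`,
#'   `counts[actual, predicted]` with dimnames `actual`/`predicted`.
#' @examples
#' confusion_from_predictions(c(0, 0, 1), c(1, 0, 1))
#' @export
confusion_from_predictions <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` must be non-empty and of equal length",
         call. = FALSE)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L)))
    stop("labels must lie in {0, 1}", call. = FALSE)
  cm <- matrix(0L, 2, 2, dimnames = list(actual = c("0", "1"),
                                         predicted = c("0", "1")))
  for (a in 0:1) for (p in 0:1)
    cm[a + 1L, p + 1L] <- sum(y_true == a & y_pred == p)
  structure(cm, class = c("confusion_2x2", "matrix", "array"))
}

new_confusion <- function(m) {
  m <- matrix(as.integer(m), 2, 2, dimnames = list(actual = c("0", "1"),
                                                   predicted = c("0", "1")))
  structure(m, class = c("confusion_2x2", "matrix", "array"))
}

#' Reconstruct a confusion matrix from a printed classification report
#'
#' For a binary problem, per-class support and recall determine the matrix
#' completely: the diagonal is `recall * support` and, with only one other
#' class, all errors land off-diagonal. The products must be integral (within
#' `tol`), otherwise the report is ambiguous and an error lists the nearest
#' integer candidates.
#'
#' @param support_0,recall_0 Support and recall of class 0 (negative).
#' @param support_1,recall_1 Support and recall of class 1 (positive).
#' @param tol Integrality tolerance for `recall * support`.
#' @return A `confusion_2x2` matrix.
#' @examples
#' reconstruct_confusion_from_report(50, 0.96, 52, 1.00)
#' @export
reconstruct_confusion_from_report <- function(support_0, recall_0,
                                              support_1, recall_1,
                                              tol = 1e-6) {
  d0 <- recall_0 * support_0
  d1 <- recall_1 * support_1
  if (abs(d0 - round(d0)) > tol || abs(d1 - round(d1)) > tol)
    stop(sprintf(
      "recall x support is not integral (%.6f, %.6f); nearest candidates %d and %d",
      d0, d1, round(d0), round(d1)), call. = FALSE)
  d0 <- round(d0); d1 <- round(d1)
  new_confusion(matrix(c(d0, support_1 - d1, support_0 - d0, d1), 2, 2))
}

warn0 <- function(num, den, what) {
  if (den == 0) {
    warning(what, " has zero denominator; returning 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Compute the full metric battery
#'
#' From a 2x2 confusion matrix: accuracy, per-class precision/recall/F1 with
#' macro and support-weighted averages, balanced accuracy, Matthews
#' correlation coefficient, Cohen's kappa, Jaccard score of the positive
#' class, specificity, sensitivity, Youden's J and the G-mean. When per-sample
#' positive-class probabilities (and their true labels) are supplied, the
#' Brier score, log loss (probabilities clipped at 1e-15) and ROC AUC are
#' added; without scores those three are returned as `NA` -- an explicit
#' "unavailable" marker, never a silent zero.
#'
#' Zero-denominator conventions: precision/recall are 0 with a warning when
#' undefined, and the MCC is 0 when any marginal is 0.
#'
#' @param cm A `confusion_2x2` (or plain 2x2 matrix, `counts[actual,
#'   predicted]`).
#' @param scores Optional vector of positive-class probabilities.
#' @param y_true True labels matching `scores` (required with `scores`).
#' @return An object of class `abisa_metrics`: a list of metric values plus a
#'   `per_class` data frame.
#' @examples
#' cm <- reconstruct_confusion_from_report(50, 0.96, 52, 1.00)
#' m <- compute_metrics(cm)
#' round(m$mcc, 2)
#' @export
compute_metrics <- function(cm, scores = NULL, y_true = NULL) {
  cm <- matrix(as.numeric(cm), 2, 2)
  if (any(cm < 0) || sum(cm) < 1)
    stop("confusion matrix needs non-negative counts summing to >= 1",
         call. = FALSE)
  tn <- cm[1, 1]; fp <- cm[1, 2]; fn <- cm[2, 1]; tp <- cm[2, 2]
  n <- sum(cm)
  support <- c(tn + fp, fn + tp)
  pred_tot <- c(tn + fn, fp + tp)
  prec <- c(warn0(tn, pred_tot[1], "precision of class 0"),
            warn0(tp, pred_tot[2], "precision of class 1"))
  rec <- c(warn0(tn, support[1], "recall of class 0"),
           warn0(tp, support[2], "recall of class 1"))
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  acc <- (tp + tn) / n
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined (zero marginal); returning 0", call. = FALSE)
    0
  } else (tp * tn - fp * fn) / sqrt(mcc_den)
  pe <- sum(support * pred_tot) / n^2
  kappa <- if (pe == 1) 0 else (acc - pe) / (1 - pe)
  sens <- rec[2]; spec <- rec[1]
  out <- list(
    per_class = data.frame(class = c(0L, 1L), precision = prec,
                           recall = rec, f1 = f1,
                           support = as.integer(support)),
    accuracy = acc,
    macro_precision = mean(prec), macro_recall = mean(rec),
    macro_f1 = mean(f1),
    weighted_precision = sum(prec * support) / n,
    weighted_recall = sum(rec * support) / n,
    weighted_f1 = sum(f1 * support) / n,
    balanced_accuracy = mean(rec),
    mcc = mcc, cohens_kappa = kappa,
    jaccard = warn0(tp, tp + fp + fn, "Jaccard"),
    specificity = spec, sensitivity = sens,
    youden_j = sens + spec - 1,
    g_mean = sqrt(sens * spec),
    brier = NA_real_, log_loss = NA_real_, roc_auc = NA_real_)
  if (!is.null(scores)) {
    if (is.null(y_true))
      stop("`y_true` is required alongside `scores`", call. = FALSE)
    p <- pmin(pmax(scores, 1e-15), 1 - 1e-15)
    out$brier <- mean((scores - y_true)^2)
    out$log_loss <- -mean(log(ifelse(y_true == 1, p, 1 - p)))
    out$roc_auc <- roc_curve(scores, y_true)$auc
  }
  structure(out, class = "abisa_metrics")
}

#' @export
print.abisa_metrics <- function(x, digits = 2, ...) {
  cat("Per-class report:\n")
  pc <- x$per_class
  pc[2:4] <- lapply(pc[2:4], round, digits)
  print(pc, row.names = FALSE)
  scalars <- x[setdiff(names(x), "per_class")]
  cat("\n")
  for (nm in names(scalars)) {
    v <- scalars[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                ifelse(is.na(v), "unavailable (needs scores)",
                       format(round(v, digits), nsmall = digits))))
  }
  invisible(x)
}

#' ROC curve and AUC
#'
#' Thresholds are placed at the distinct score values (classifying a sample
#' positive when its score is >= the threshold), which yields a monotone
#' non-decreasing curve from (0, 0) to (1, 1); the AUC is the trapezoidal
#' area under it. Tied scores move along the curve diagonally, so identical
#' scores for all samples give AUC 0.5.
#'
#' @param scores Positive-class scores.
#' @param y_true Labels over \{0, 1\}; both classes must be present.
#' @return List with `fpr`, `tpr`, `thresholds` and `auc`.
#' @export
roc_curve <- function(scores, y_true) {
  if (length(scores) != length(y_true))
    stop("`scores` and `y_true` must have equal length", call. = FALSE)
  np <- sum(y_true == 1); nn <- sum(y_true == 0)
  if (np == 0 || nn == 0)
    stop("ROC needs at least one positive and one negative sample",
         call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y_true[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- which(!duplicated(s, fromLast = TRUE))   # last index of each tie group
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, s[last]), auc = auc)
}

#' Round a metrics report for display
#'
#' Display helper mirroring the 2-decimal rounding used in printed
#' classification reports; computation always keeps full precision.
#'
#' @param metrics An `abisa_metrics` object.
#' @param digits Decimal places.
#' @return Named numeric vector of rounded scalar metrics.
#' @export
format_report <- function(metrics, digits = 2) {
  scalars <- metrics[setdiff(names(metrics), "per_class")]
  round(unlist(scalars), digits)
}
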