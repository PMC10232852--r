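#' Confusion counts for binary predictions
#'
#' Standard 2x2 counting with label 1 as the positive class.
#'
#' @param labels true 0/1 labels.
#' @param predicted predicted 0/1 labels.
#' @return A `confusion_counts` list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(labels, predicted) {
  stopifnot(length(labels) == length(predicted))
  labels <- as.integer(labels)
  predicted <- as.integer(predicted)
  if (!all(labels %in% 0:1) || !all(predicted %in% 0:1)) {
    stop("labels and predictions must be binary 0/1", call. = FALSE)
  }
  structure(list(TP = sum(labels == 1L & predicted == 1L),
                 FP = sum(labels == 0L & predicted == 1L),
                 TN = sum(labels == 0L & predicted == 0L),
                 FN = sum(labels == 1L & predicted == 0L)),
            class = "confusion_counts")
}

confusion_counts <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0, TP + FP + TN + FN >= 1)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2L, 2L,
              dimnames = list(c("pred 1", "pred 0"), c("true 1", "true 0")))
  print(m)
  invisible(x)
}

# Shared convention: a degenerate denominator yields 0 with a warning, so
# heavily imbalanced evaluations stay total instead of crashing.
safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s is undefined (zero denominator); returning 0", what),
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Confusion-count metrics
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, F-value `2TP/(2TP+FP+FN)` and Matthews correlation
#' coefficient.  Degenerate denominators return 0 with a warning.
#'
#' @param c a `confusion_counts` object.
#' @name confusion_metrics
NULL

#' @rdname confusion_metrics
#' @export
accuracy <- function(c) {
  (c$TP + c$TN) / (c$TP + c$FP + c$TN + c$FN)
}

#' @rdname confusion_metrics
#' @export
precision <- function(c) safe_ratio(c$TP, c$TP + c$FP, "precision")

#' @rdname confusion_metrics
#' @export
recall <- function(c) safe_ratio(c$TP, c$TP + c$FN, "recall")

#' @rdname confusion_metrics
#' @export
f_value <- function(c) safe_ratio(2 * c$TP, 2 * c$TP + c$FP + c$FN, "F-value")

#' @rdname confusion_metrics
#' @export
mcc <- function(c) {
  tp <- as.numeric(c$TP); tn <- as.numeric(c$TN)
  fp <- as.numeric(c$FP); fn <- as.numeric(c$FN)
  den <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
  if (den == 0) {
    warning("MCC is undefined (empty margin); returning 0", call. = FALSE)
    return(0)
  }
  (tp * tn - fn * fp) / den
}

# Threshold sweep shared by the ROC and PR curves: thresholds are the unique
# scores in descending order; ties fall into the same threshold group.
sweep_thresholds <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  if (!all(labels %in% 0:1)) stop("labels must be binary 0/1", call. = FALSE)
  P <- sum(labels == 1L)
  N <- sum(labels == 0L)
  if (P == 0L || N == 0L) {
    stop("need at least one positive and one negative label", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  ls <- labels[ord]
  ss <- scores[ord]
  grp <- cumsum(!duplicated(ss))
  tp <- cumsum(ls == 1L)
  fp <- cumsum(ls == 0L)
  last <- which(!duplicated(grp, fromLast = TRUE))
  list(threshold = thr, tp = tp[last], fp = fp[last], P = P, N = N)
}

#' ROC curve
#'
#' Sweeps thresholds over the unique scores (descending, ties grouped) and
#' returns (FPR, TPR) points, anchored at (0,0) and (1,1).
#'
#' @param labels binary 0/1 labels.
#' @param scores real-valued scores (larger = more positive).
#' @return A `curve_points` data frame with columns `x` (FPR), `y` (TPR) and
#'   `threshold`.
#' @export
roc_curve <- function(labels, scores) {
  s <- sweep_thresholds(labels, scores)
  out <- data.frame(x = c(0, s$fp / s$N, 1),
                    y = c(0, s$tp / s$P, 1),
                    threshold = c(Inf, s$threshold, -Inf))
  out <- out[!duplicated(out[, c("x", "y")]), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, kind = "roc", class = c("curve_points", "data.frame"))
}

#' Precision-recall curve
#'
#' Same threshold sweep as [roc_curve()]; returns (recall, precision) points.
#'
#' @inheritParams roc_curve
#' @export
pr_curve <- function(labels, scores) {
  s <- sweep_thresholds(labels, scores)
  prec <- s$tp / (s$tp + s$fp)
  rec <- s$tp / s$P
  out <- data.frame(x = rec, y = prec, threshold = s$threshold)
  rownames(out) <- NULL
  structure(out, kind = "pr", class = c("curve_points", "data.frame"))
}

#' Areas under the ROC and PR curves
#'
#' `auroc()` integrates the ROC curve with the trapezoid rule (equal to the
#' concordance probability with ties counted half).  `aupr()` uses the step
#' (precision-at-recall) convention, which avoids the optimistic bias of
#' trapezoidal PR interpolation.
#'
#' @inheritParams roc_curve
#' @export
auroc <- function(labels, scores) {
  pts <- roc_curve(labels, scores)
  sum(diff(pts$x) * (utils::head(pts$y, -1) + pts$y[-1]) / 2)
}

#' @rdname auroc
#' @export
aupr <- function(labels, scores) {
  pts <- pr_curve(labels, scores)
  sum(diff(c(0, pts$x)) * pts$y)
}

#' Full metric report at a decision threshold
#'
#' The seven-metric suite (ACC, PRE, F-value, recall, MCC, auROC, auPR) plus
#' the underlying confusion counts.
#'
#' @param labels binary 0/1 labels.
#' @param scores predicted probabilities.
#' @param threshold classification threshold (default 0.5, ties positive).
#' @return A `metric_report`.
#' @export
metric_report <- function(labels, scores, threshold = 0.5) {
  cts <- confusion(labels, predict_class(scores, threshold))
  structure(list(acc = accuracy(cts), pre = precision(cts),
                 f_value = f_value(cts), recall = recall(cts), mcc = mcc(cts),
                 auroc = auroc(labels, scores), aupr = aupr(labels, scores),
                 counts = cts, n = length(labels), threshold = threshold),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4L, ...) {
  cat(sprintf("<metric_report> n = %d, threshold = %g\n", x$n, x$threshold))
  vals <- c(ACC = x$acc, PRE = x$pre, `F-value` = x$f_value,
            Recall = x$recall, MCC = x$mcc, auROC = x$auroc, auPR = x$aupr)
  for (nm in names(vals)) cat(sprintf("  %-8s %.*f\n", nm, digits, vals[nm]))
  print(x$counts)
  invisible(x)
}

#' Serialise a metric report to JSON
#'
#' @param report a `metric_report`.
#' @param path optional output path; when NULL the JSON string is returned.
#' @export
write_metric_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "metric_report"))
  obj <- list(acc = report$acc, pre = report$pre, f_value = report$f_value,
              recall = report$recall, mcc = report$mcc, auroc = report$auroc,
              aupr = report$aupr,
              counts = unclass(report$counts), n = report$n,
              threshold = report$threshold)
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write curve points as a two-column CSV
#'
#' @param curve a `curve_points` data frame.
#' @param path output path.
#' @export
write_curve <- function(curve, path) {
  utils::write.table(curve[, c("x", "y")], path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
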