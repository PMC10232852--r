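# Independent loop-based oracle: count the four cells pair by pair.
oracle_confusion <- function(labels, preds) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(labels)) {
    if (labels[i] == 1L && preds[i] == 1L) tp <- tp + 1L
    else if (labels[i] == 0L && preds[i] == 1L) fp <- fp + 1L
    else if (labels[i] == 0L && preds[i] == 0L) tn <- tn + 1L
    else fn <- fn + 1L
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# Exhaustive concordance-pair oracle for the ROC area.
oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

test_that("confusion counting matches the pairwise oracle", {
  withr::with_seed(5, {
    for (rep in 1:50) {
      n <- sample(5:60, 1)
      labels <- rbinom(n, 1, 0.5)
      preds <- rbinom(n, 1, 0.5)
      cts <- confusion(labels, preds)
      o <- oracle_confusion(labels, preds)
      expect_identical(unlist(cts[c("TP", "FP", "TN", "FN")]), o)
    }
  })
  cts <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cts)[c("TP", "FN", "TN", "FP")],
               list(TP = 1L, FN = 1L, TN = 1L, FP = 1L))
  all_right <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(all_right$FP + all_right$FN, 0L)
  expect_error(confusion(c(1, 0), c(1)), "length")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("the worked 36-of-41 example gives 87.80% accuracy", {
  cts <- deepm5U:::confusion_counts(TP = 36, FP = 0, TN = 0, FN = 5)
  expect_equal(round(100 * accuracy(cts), 2), 87.80)
  expect_equal(accuracy(cts), 36 / 41)
})

test_that("count metrics follow the printed formulas on edge tables", {
  perfect <- deepm5U:::confusion_counts(TP = 10, FP = 0, TN = 10, FN = 0)
  for (f in list(accuracy, precision, recall, f_value, mcc)) {
    expect_equal(f(perfect), 1)
  }
  chance <- deepm5U:::confusion_counts(TP = 25, FP = 25, TN = 25, FN = 25)
  expect_equal(mcc(chance), 0)
  expect_equal(accuracy(chance), 0.5)

  degen <- deepm5U:::confusion_counts(TP = 0, FP = 0, TN = 5, FN = 5)
  expect_warning(expect_equal(precision(degen), 0), "undefined")
  expect_warning(expect_equal(mcc(degen), 0), "undefined")
})

test_that("count metrics match a formula oracle on random tables", {
  withr::with_seed(11, {
    for (rep in 1:200) {
      v <- sample(0:40, 4, replace = TRUE)
      if (sum(v) == 0) v[1] <- 1
      cts <- deepm5U:::confusion_counts(v[1], v[2], v[3], v[4])
      tp <- v[1]; fp <- v[2]; tn <- v[3]; fn <- v[4]
      expect_equal(accuracy(cts), (tp + tn) / sum(v))
      num <- tp * tn - fn * fp
      den <- sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tp + fp)) * sqrt((tn + fn))
      suppressWarnings({
        expect_equal(precision(cts), if (tp + fp == 0) 0 else tp / (tp + fp))
        expect_equal(recall(cts), if (tp + fn == 0) 0 else tp / (tp + fn))
        expect_equal(f_value(cts),
                     if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
        expect_equal(mcc(cts), if (den == 0) 0 else num / den)
      })
    }
  })
})

test_that("MCC antisymmetry and ACC label-exchange invariance hold", {
  withr::with_seed(23, {
    for (rep in 1:25) {
      n <- 40
      labels <- rbinom(n, 1, 0.5)
      preds <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2 || length(unique(preds)) < 2) next
      c1 <- confusion(labels, preds)
      c2 <- confusion(labels, 1L - preds)
      expect_equal(mcc(c2), -mcc(c1), tolerance = 1e-12)
      swapped <- deepm5U:::confusion_counts(c1$TN, c1$FN, c1$TP, c1$FP)
      expect_equal(accuracy(swapped), accuracy(c1))
    }
  })
})

test_that("ROC endpoints, tie handling and degenerate curves are correct", {
  labels <- c(1, 1, 0, 0)
  perfect <- roc_curve(labels, c(0.9, 0.8, 0.2, 0.1))
  expect_true(any(perfect$x == 0 & perfect$y == 1))
  expect_equal(perfect$x[1], 0); expect_equal(perfect$y[1], 0)
  expect_equal(tail(perfect$x, 1), 1); expect_equal(tail(perfect$y, 1), 1)
  expect_true(all(diff(perfect$x) >= 0))

  flat <- roc_curve(labels, rep(0.5, 4))
  expect_equal(as.matrix(flat[, c("x", "y")]),
               rbind(c(0, 0), c(1, 1)), ignore_attr = TRUE)
  expect_equal(auroc(labels, rep(0.5, 4)), 0.5)

  scores <- withr::with_seed(3, runif(30))
  lab <- rep(c(1, 0), 15)
  expect_lte(nrow(roc_curve(lab, scores)), length(unique(scores)) + 1L)
  expect_error(roc_curve(c(1, 1), c(0.5, 0.4)), "one positive and one negative")
})

test_that("auROC equals the exhaustive concordance-pair oracle", {
  expect_equal(auroc(c(1, 1, 0), c(0.9, 0.8, 0.1)), 1.0)
  expect_equal(auroc(c(0, 0, 1), c(0.9, 0.8, 0.1)), 0.0)
  withr::with_seed(7, {
    for (rep in 1:50) {
      n <- sample(4:50, 1)
      labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
      scores <- round(runif(n), 2)  # rounded to force ties
      expect_equal(auroc(labels, scores), oracle_auroc(labels, scores),
                   tolerance = 1e-12)
    }
  })
})

test_that("PR curve and step-interpolated area behave on known cases", {
  labels <- c(1, 1, 0, 0)
  expect_equal(aupr(labels, c(0.9, 0.8, 0.2, 0.1)), 1.0)
  # one positive ranked last among n: AP = 1/n
  expect_equal(aupr(c(0, 0, 0, 1), c(0.9, 0.8, 0.7, 0.1)), 0.25)
  pr <- pr_curve(labels, c(0.9, 0.3, 0.8, 0.1))
  expect_true(all(pr$y >= 0 & pr$y <= 1))
  expect_equal(tail(pr$x, 1), 1)  # lowest threshold recalls everything
})

test_that("roc/pr areas agree with the pROC package on a random instance", {
  skip_if_not_installed("pROC")
  withr::with_seed(19, {
    labels <- rbinom(200, 1, 0.4)
    scores <- runif(200) + 0.5 * labels
  })
  ours <- auroc(labels, scores)
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("metric reports carry the full seven-metric suite and serialize", {
  withr::with_seed(2, {
    labels <- rbinom(100, 1, 0.5)
    scores <- pmin(pmax(labels * 0.6 + runif(100) * 0.5, 0), 1)
  })
  rep_ <- metric_report(labels, scores)
  expect_s3_class(rep_, "metric_report")
  expect_equal(rep_$n, 100L)
  expect_equal(rep_$counts$TP + rep_$counts$FP + rep_$counts$TN +
                 rep_$counts$FN, 100L)
  json <- jsonlite::fromJSON(write_metric_report(rep_))
  expect_setequal(names(json),
                  c("acc", "pre", "f_value", "recall", "mcc", "auroc", "aupr",
                    "counts", "n", "threshold"))
  expect_equal(json$acc, rep_$acc)

  path <- withr::local_tempfile(fileext = ".csv")
  write_curve(roc_curve(labels, scores), path)
  curve <- utils::read.table(path, header = TRUE, sep = ",")
  expect_equal(colnames(curve), c("x", "y"))
  expect_gt(nrow(curve), 2)
})
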