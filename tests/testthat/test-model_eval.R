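test_that("metrics match hand arithmetic on a fixed confusion table", {
  # TP=50, FP=10, TN=40, FN=0
  labels <- c(rep(1L, 50), rep(0L, 50))
  preds <- c(rep(1L, 50), rep(1L, 10), rep(0L, 40))
  r <- compute_metrics(labels, preds)
  expect_equal(unname(r$counts), c(50L, 10L, 40L, 0L))
  expect_equal(unname(r$metrics["PRE"]), 50 / 60, tolerance = 1e-12)
  expect_equal(unname(r$metrics["REC"]), 1)
  expect_equal(unname(r$metrics["SPE"]), 0.8)
  expect_equal(unname(r$metrics["ACC"]), 0.9)
  expect_equal(unname(r$metrics["F1"]), 2 * (50 / 60) / (50 / 60 + 1),
               tolerance = 1e-12)
  expect_equal(round(unname(r$metrics[c("PRE", "F1")]), 4),
               c(0.8333, 0.9091))
})

test_that("degenerate predictors surface undefined metrics, not zeros", {
  # perfect prediction
  r <- compute_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(unname(r$metrics[c("ACC", "MCC", "F1")]), c(1, 1, 1))
  # all-positive predictions on balanced labels
  r2 <- compute_metrics(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(unname(r2$metrics["SPE"]), 0)
  expect_equal(unname(r2$metrics["REC"]), 1)
  # no predicted positives -> PRE undefined (NA), flagged
  r3 <- compute_metrics(c(1, 0), c(0, 0))
  expect_true(is.na(r3$metrics["PRE"]))
  expect_true("PRE" %in% r3$undefined)
  # single-class labels -> MCC denominator 0 -> 0 by convention, flagged
  r4 <- compute_metrics(c(1, 1), c(1, 0))
  expect_equal(unname(r4$metrics["MCC"]), 0)
  expect_true("MCC" %in% r4$undefined)
  expect_error(compute_metrics(1, c(1, 0)), "length")
})

test_that("metrics equal brute-force confusion counting on random vectors", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    preds <- rbinom(n, 1, runif(1, 0.2, 0.8))
    r <- compute_metrics(labels, preds)
    tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
    for (k in seq_len(n)) {
      if (labels[k] == 1 && preds[k] == 1) tp <- tp + 1L
      if (labels[k] == 0 && preds[k] == 1) fp <- fp + 1L
      if (labels[k] == 0 && preds[k] == 0) tn <- tn + 1L
      if (labels[k] == 1 && preds[k] == 0) fn <- fn + 1L
    }
    expect_equal(unname(r$counts), c(tp, fp, tn, fn))
    expect_equal(sum(r$counts), n)
    if (!is.na(r$metrics["PRE"])) {
      expect_equal(unname(r$metrics["PRE"]), tp / (tp + fp))
    }
    if (tp + fp > 0 && tp + fn > 0 && tn + fp > 0 && tn + fn > 0) {
      expect_equal(unname(r$metrics["MCC"]),
                   (tp * tn - fp * fn) /
                     sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn))),
                   tolerance = 1e-12)
    }
    # identity: ACC = (REC * Npos + SPE * Nneg) / n
    npos <- sum(labels == 1); nneg <- n - npos
    if (npos > 0 && nneg > 0) {
      expect_equal(unname(r$metrics["ACC"]),
                   unname(r$metrics["REC"] * npos + r$metrics["SPE"] * nneg) /
                     n,
                   tolerance = 1e-12)
    }
  }
})

test_that("AUC equals the exhaustive U-statistic oracle", {
  # perfectly separating scores
  expect_equal(roc_auc(c(1, 1, 0, 0), c(4, 3, 2, 1))$auc, 1)
  # 12-point fixture with ties
  labels <- c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.8, 0.6, 0.5, 0.3, 0.8, 0.6, 0.4, 0.4, 0.2, 0.1)
  ra <- roc_auc(labels, scores)
  expect_equal(ra$auc, u_statistic_auc(labels, scores), tolerance = 1e-12)
  # random score vectors
  set.seed(23)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    expect_equal(roc_auc(labels, scores)$auc,
                 u_statistic_auc(labels, scores), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(29)
  labels <- rbinom(50, 1, 0.5); labels[1:2] <- c(0, 1)
  scores <- rnorm(50)
  base <- roc_auc(labels, scores)$auc
  expect_equal(roc_auc(labels, exp(scores))$auc, base, tolerance = 1e-12)
  expect_equal(roc_auc(labels, 5 * scores - 2)$auc, base, tolerance = 1e-12)
  expect_equal(roc_auc(labels, atan(scores))$auc, base, tolerance = 1e-12)
})

test_that("ROC endpoints and label-independent scores behave as expected", {
  set.seed(31)
  labels <- rbinom(2000, 1, 0.5)
  labels[1:2] <- c(0, 1)
  scores <- rnorm(2000)
  ra <- roc_auc(labels, scores)
  expect_equal(ra$roc$FPR[1], 0); expect_equal(ra$roc$TPR[1], 0)
  expect_equal(ra$roc$FPR[nrow(ra$roc)], 1)
  expect_equal(ra$roc$TPR[nrow(ra$roc)], 1)
  expect_lt(abs(ra$auc - 0.5), 0.05)
})

test_that("RBF classifier separates a separable toy problem and emits scores", {
  set.seed(37)
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 4), 50, 2))
  y <- rep(c(0L, 1L), each = 50)
  clf <- train_classifier(x, y, seed = 1L)
  pred <- predict(clf, x)
  expect_equal(mean(pred$label == y), 1)
  # scores rank the classes
  expect_equal(roc_auc(y, pred$score)$auc, 1)
  expect_error(train_classifier(x, rep(1L, 100)), "single class")
})

test_that("held-out accuracy on a planted two-cluster set exceeds 0.95", {
  set.seed(41)
  n <- 200
  centre <- rep(c(0, 3), each = n / 2)
  x <- matrix(rnorm(n * 8, centre, 1), n, 8)
  y <- rep(c(0L, 1L), each = n / 2)
  tr <- sort(c(sample(which(y == 0), 80), sample(which(y == 1), 80)))
  clf <- train_classifier(x[tr, ], y[tr], seed = 2L)
  pred <- predict(clf, x[-tr, ])
  expect_gt(mean(pred$label == y[-tr]), 0.95)
})

test_that("evaluation reports serialize to JSON and TSV", {
  r <- evaluate_predictions(c(1, 0, 1, 0), c(1, 0, 0, 0),
                            c(0.9, 0.2, 0.4, 0.1))
  fj <- withr::local_tempfile(fileext = ".json")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_report(r, fj)
  parsed <- jsonlite::read_json(fj)
  expect_equal(parsed$counts$TP, 1L)
  expect_equal(parsed$auc, r$auc)
  write_report(r, ft)
  lines <- readLines(ft)
  expect_equal(length(lines), 2L)
  expect_match(lines[1], "AUC")
})
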