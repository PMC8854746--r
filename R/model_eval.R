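#' Train the RBF-kernel classifier on pair features
#'
#' Features are standardized to zero mean / unit variance using training
#' statistics only, then a C-SVM with a radial-basis-function kernel is
#' fitted. The returned handle predicts both hard labels and continuous
#' decision scores (needed for ROC/AUC).
#'
#' @param x numeric matrix of pair features (rows = pairs).
#' @param labels binary integer vector (0/1), same length as `nrow(x)`.
#' @param C soft-margin cost (default 1).
#' @param gamma kernel width; the default `"scale"` uses
#'   `1 / (ncol(x) * var(x_standardized))`.
#' @param seed integer seed (the SVM fit itself is deterministic; the seed
#'   fixes any tie-breaking randomness).
#' @return An `lpi_classifier` handle.
#' @export
train_classifier <- function(x, labels = NULL, C = 1, gamma = "scale",
                             seed = 1L) {
  if (inherits(x, "pair_feature_set") && is.null(labels)) {
    labels <- attr(x, "labels")
  }
  x <- unclass(x)
  attr(x, "pairs") <- NULL; attr(x, "labels") <- NULL
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(labels) || length(labels) != nrow(x)) {
    stop("`labels` must match the number of feature rows", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  centre <- colMeans(x)
  scale_ <- apply(x, 2L, sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- sweep(sweep(x, 2L, centre), 2L, scale_, "/")
  if (identical(gamma, "scale")) {
    v <- mean(apply(xs, 2L, var))
    gamma <- 1 / (ncol(xs) * max(v, .Machine$double.eps))
  }
  fit <- local_seed(seed, {
    e1071::svm(xs, factor(labels, levels = c(0L, 1L)), type = "C-classification",
               kernel = "radial", cost = C, gamma = gamma, scale = FALSE,
               probability = FALSE)
  })
  structure(list(fit = fit, centre = centre, scale = scale_, gamma = gamma,
                 C = C),
            class = "lpi_classifier")
}

#' Predict labels and decision scores for pair features
#'
#' @param object an `lpi_classifier`.
#' @param newdata numeric matrix of pair features.
#' @param ... unused.
#' @return data.frame with columns `score` (continuous decision value,
#'   oriented so larger means more likely positive) and `label` (0/1).
#' @export
predict.lpi_classifier <- function(object, newdata, ...) {
  x <- unclass(newdata)
  attr(x, "pairs") <- NULL; attr(x, "labels") <- NULL
  xs <- sweep(sweep(x, 2L, object$centre), 2L, object$scale, "/")
  pr <- predict(object$fit, xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  score <- dv[, 1L]
  # e1071 orients decision values towards the first class seen in training;
  # flip so that higher score = class "1"
  if (grepl("^0/", colnames(dv)[1L])) score <- -score
  data.frame(score = as.numeric(score),
             label = as.integer(as.character(pr)),
             row.names = NULL)
}

#' Confusion counts and classification metrics
#'
#' Computes TP/FP/TN/FN and precision, recall, specificity, accuracy,
#' Matthews correlation coefficient and F1:
#' `PRE = TP/(TP+FP)`, `REC = TP/(TP+FN)`, `SPE = TN/(FP+TN)`,
#' `ACC = (TP+TN)/n`, `MCC = (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' `F1 = 2*PRE*REC/(PRE+REC)`. A metric whose denominator is zero is
#' reported as `NA` (undefined) and listed in the `undefined` field, except
#' MCC which falls back to 0 by convention (and is flagged).
#'
#' @param labels binary vector of true labels.
#' @param predictions binary vector of predicted labels.
#' @return An `evaluation_report` list with fields `counts` (TP, FP, TN, FN)
#'   and `metrics` (PRE, REC, SPE, ACC, MCC, F1), plus `undefined`.
#' @export
compute_metrics <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("labels and predictions differ in length", call. = FALSE)
  }
  if (length(labels) == 0L) stop("empty input", call. = FALSE)
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  stopifnot(all(labels %in% 0:1), all(predictions %in% 0:1))
  tp <- sum(labels == 1L & predictions == 1L)
  fp <- sum(labels == 0L & predictions == 1L)
  tn <- sum(labels == 0L & predictions == 0L)
  fn <- sum(labels == 1L & predictions == 0L)
  undef <- character()
  safe_div <- function(num, den, name) {
    if (den == 0) {
      undef <<- c(undef, name)
      return(NA_real_)
    }
    num / den
  }
  pre <- safe_div(tp, tp + fp, "PRE")
  rec <- safe_div(tp, tp + fn, "REC")
  spe <- safe_div(tn, fp + tn, "SPE")
  acc <- (tp + tn) / (tp + fp + tn + fn)
  mcc_den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (mcc_den == 0) {
    undef <- c(undef, "MCC")
    0
  } else {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  }
  f1 <- if (is.na(pre) || is.na(rec) || (pre + rec) == 0) {
    undef <- c(undef, "F1")
    NA_real_
  } else {
    2 * pre * rec / (pre + rec)
  }
  structure(list(
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
    metrics = c(PRE = pre, REC = rec, SPE = spe, ACC = acc, MCC = mcc,
                F1 = f1),
    undefined = unique(undef)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat("  counts: ", paste(sprintf("%s=%d", names(x$counts), x$counts),
                          collapse = " "), "\n")
  cat("  metrics:", paste(sprintf("%s=%.4f", names(x$metrics), x$metrics),
                          collapse = " "), "\n")
  if (!is.null(x$auc)) cat(sprintf("  AUC=%.4f\n", x$auc))
  if (length(x$undefined) > 0L) {
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' ROC curve and AUC from continuous scores
#'
#' The ROC curve is built by sweeping every distinct score as a threshold
#' (ties grouped); AUC is the trapezoidal area, identical to the normalized
#' Mann-Whitney U statistic (ties counted 1/2).
#'
#' @param labels binary vector of true labels (both classes present).
#' @param scores numeric vector of continuous scores (larger = more
#'   positive).
#' @return List with `roc` (data.frame of FPR, TPR, one row per threshold
#'   plus the (0,0) anchor) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) {
    stop("labels and scores differ in length", call. = FALSE)
  }
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  # group tied scores
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(lab == 1L); fp <- cumsum(lab == 0L)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / npos)
  fpr <- c(0, fp[last] / nneg)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
  list(roc = data.frame(FPR = fpr, TPR = tpr), auc = auc)
}

#' Evaluate score-based predictions against held-out labels
#'
#' Combines [compute_metrics()] (on hard labels) with [roc_auc()] (on
#' scores) into one report.
#'
#' @param labels binary truth vector.
#' @param predicted binary predicted labels.
#' @param scores continuous decision scores.
#' @return An `evaluation_report` with `roc` and `auc` fields added.
#' @export
evaluate_predictions <- function(labels, predicted, scores) {
  rep_ <- compute_metrics(labels, predicted)
  ra <- roc_auc(labels, scores)
  rep_$roc <- ra$roc
  rep_$auc <- ra$auc
  rep_
}

#' Serialize an evaluation report
#'
#' @param report an `evaluation_report`.
#' @param path output path; `.json` writes JSON, anything else a flat TSV
#'   row (counts + metrics + AUC).
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  if (grepl("\\.json$", path)) {
    out <- list(counts = as.list(report$counts),
                metrics = as.list(report$metrics),
                auc = report$auc,
                undefined = report$undefined)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else {
    row <- c(report$counts, round(report$metrics, 6L),
             AUC = if (is.null(report$auc)) NA_real_ else
               round(report$auc, 6L))
    writeLines(c(paste(names(row), collapse = "\t"),
                 paste(row, collapse = "\t")), path)
  }
  invisible(path)
}
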