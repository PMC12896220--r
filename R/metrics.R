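#' Confusion matrix at a probability threshold
#'
#' Scores at or above the threshold are predicted positive (ties at the
#' threshold go to class 1, for bit-exact reproducibility).
#'
#' @param scores predicted class-1 probabilities in [0, 1].
#' @param labels integer 0/1 vector.
#' @param threshold decision threshold (default 0.5).
#' @return An object of class `confusion_matrix` with integer fields
#'   `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0L) stop("confusion: empty input")
  stopifnot(length(scores) == length(labels))
  if (any(scores < 0 | scores > 1)) stop("confusion: scores must be in [0, 1]")
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  structure(list(TP = sum(pred == 1L & labels == 1L),
                 TN = sum(pred == 0L & labels == 0L),
                 FP = sum(pred == 1L & labels == 0L),
                 FN = sum(pred == 0L & labels == 1L)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> TP", x$TP, "FN", x$FN, "FP", x$FP, "TN", x$TN, "\n")
  invisible(x)
}

#' Accuracy, sensitivity, specificity and F1 from a confusion matrix
#'
#' acc = (TP+TN)/(TP+TN+FP+FN); sen = TP/(TP+FN); spe = TN/(TN+FP);
#' f1 = 2TP/(2TP+FP+FN). A zero denominator yields `NaN` with a warning,
#' never a silent 0.
#'
#' @param cm a [confusion()] result.
#' @return Named numeric vector `c(acc, sen, spe, f1)`.
#' @export
metrics_from_cm <- function(cm) {
  n <- cm$TP + cm$TN + cm$FP + cm$FN
  if (n == 0L) stop("metrics_from_cm: empty confusion matrix")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("metrics_from_cm: ", what, " undefined (zero denominator)")
      return(NaN)
    }
    num / den
  }
  c(acc = (cm$TP + cm$TN) / n,
    sen = safe_div(cm$TP, cm$TP + cm$FN, "sensitivity"),
    spe = safe_div(cm$TN, cm$TN + cm$FP, "specificity"),
    f1 = safe_div(2 * cm$TP, 2 * cm$TP + cm$FP + cm$FN, "F1"))
}

#' Rank-based (Mann-Whitney) AUC with tie correction
#'
#' `P(score+ > score-) + 0.5 P(score+ = score-)`, computed from midranks.
#'
#' @param scores predicted class-1 scores.
#' @param labels integer 0/1 vector with both classes present.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("auc: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

metric_value <- function(metric, scores, labels, threshold) {
  if (is.function(metric)) return(metric(scores, labels))
  switch(metric,
         auc = auc(scores, labels),
         acc = metrics_from_cm(confusion(scores, labels, threshold))[["acc"]],
         sen = metrics_from_cm(confusion(scores, labels, threshold))[["sen"]],
         spe = metrics_from_cm(confusion(scores, labels, threshold))[["spe"]],
         f1 = metrics_from_cm(confusion(scores, labels, threshold))[["f1"]],
         stop("unknown metric: ", metric))
}

#' Percentile-bootstrap confidence interval for a classification metric
#'
#' Resamples (score, label) pairs with replacement and takes the 2.5 and
#' 97.5 percentiles of the metric's bootstrap distribution. Replicates in
#' which only one class survives are skipped and counted; more than 50%
#' degenerate replicates is an error.
#'
#' @param scores predicted class-1 scores.
#' @param labels integer 0/1 vector (n >= 10).
#' @param metric `"auc"`, `"acc"`, `"sen"`, `"spe"`, `"f1"`, or a function
#'   `(scores, labels) -> value`.
#' @param replicates number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param threshold decision threshold for thresholded metrics.
#' @param level confidence level (default 0.95).
#' @return List with `lo`, `hi`, `n_degenerate`.
#' @export
bootstrap_ci <- function(scores, labels, metric = "auc", replicates = 1000L,
                         seed = 0L, threshold = 0.5, level = 0.95) {
  n <- length(scores)
  if (n < 10L) stop("bootstrap_ci: need n >= 10")
  labels <- as.integer(labels)
  vals <- numeric(0)
  n_degen <- 0L
  with_seed(derive_seed(seed, "bootstrap"), {
    for (b in seq_len(replicates)) {
      ix <- sample.int(n, n, replace = TRUE)
      lb <- labels[ix]
      if (sum(lb == 1L) == 0L || sum(lb == 0L) == 0L) {
        n_degen <- n_degen + 1L
        next
      }
      vals[length(vals) + 1L] <- suppressWarnings(
        metric_value(metric, scores[ix], lb, threshold))
    }
  })
  if (n_degen > replicates / 2) {
    stop("bootstrap_ci: > 50% of replicates were single-class; ",
         "data too small or too imbalanced")
  }
  qs <- quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                 na.rm = TRUE, names = FALSE, type = 7)
  list(lo = qs[1], hi = qs[2], n_degenerate = n_degen)
}

#' Evaluate a trained model on a test partition
#'
#' Computes AUC, accuracy, sensitivity, specificity and F1 with percentile
#' bootstrap 95% confidence intervals.
#'
#' @param model a `glnet_model` (or a `glnet_fit`).
#' @param dataset a standardized `encoded_dataset` with labels.
#' @param idx row indices of the test partition (default: all rows).
#' @param threshold decision threshold on the class-1 probability.
#' @param replicates bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return An object of class `metrics_report`: per-metric point estimates
#'   and CIs (fraction scale), `n`, `threshold`, bootstrap config, and the
#'   raw `scores`/`labels`.
#' @export
evaluate <- function(model, dataset, idx = NULL, threshold = 0.5,
                     replicates = 1000L, seed = 0L) {
  if (inherits(model, "glnet_fit")) model <- model$model
  if (is.null(idx)) idx <- seq_len(nrow(dataset$x))
  if (length(idx) == 0L) stop("evaluate: empty test set")
  scores <- predict_proba(dataset$x[idx, , drop = FALSE], model)
  labels <- dataset$y[idx]
  cm <- confusion(scores, labels, threshold)
  pt <- suppressWarnings(metrics_from_cm(cm))
  metrics <- list()
  for (m in c("auc", "acc", "sen", "spe", "f1")) {
    point <- if (m == "auc") auc(scores, labels) else pt[[m]]
    ci <- bootstrap_ci(scores, labels, m, replicates = replicates,
                       seed = seed, threshold = threshold)
    metrics[[m]] <- list(point = point, lo = ci$lo, hi = ci$hi)
  }
  structure(list(metrics = metrics, confusion = cm, n = length(idx),
                 threshold = threshold,
                 bootstrap = list(replicates = as.integer(replicates),
                                  seed = as.integer(seed)),
                 scores = scores, labels = labels),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> n =", x$n, " threshold =", x$threshold, "\n")
  for (m in names(x$metrics)) {
    v <- x$metrics[[m]]
    cat(sprintf("  %-4s %6.2f%%  (95%% CI %.2f-%.2f)\n", toupper(m),
                100 * v$point, 100 * v$lo, 100 * v$hi))
  }
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' Writes every metric in both fraction and percent scale, with its CI and
#' the bootstrap configuration.
#'
#' @param report a `metrics_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  obj <- list(n = report$n, threshold = report$threshold,
              bootstrap = report$bootstrap,
              confusion = unclass(report$confusion),
              metrics = lapply(report$metrics, function(v) {
                list(fraction = list(point = v$point, lo = v$lo, hi = v$hi),
                     percent = list(point = 100 * v$point, lo = 100 * v$lo,
                                    hi = 100 * v$hi))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
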