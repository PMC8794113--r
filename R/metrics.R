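#' Confusion counts at a threshold
#'
#' Applies the decision rule "score >= threshold => positive" (the
#' boundary score is classified positive) and tallies the confusion
#' matrix.
#'
#' @param labels 0/1 labels.
#' @param scores Scores in \[0, 1\].
#' @param threshold Decision threshold in \[0, 1\].
#' @return An object of class `confusion_counts`: a list with integer
#'   fields `tp`, `fp`, `tn`, `fn` and the `threshold`.
#' @examples
#' confusion(c(1, 0), c(0.5, 0.5), 0.5)  # boundary counts as positive
#' @export
confusion <- function(labels, scores, threshold) {
  if (length(labels) != length(scores)) {
    stop_invalid("labels and scores must have equal length")
  }
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    stop_invalid("threshold must be a single number in [0, 1]")
  }
  if (!all(labels %in% c(0, 1))) stop_invalid("labels must be 0/1")
  pred <- scores >= threshold
  structure(
    list(
      tp = sum(pred & labels == 1),
      fp = sum(pred & labels == 0),
      tn = sum(!pred & labels == 0),
      fn = sum(!pred & labels == 1),
      threshold = threshold
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(
    "<confusion_counts> t = %g: TP %d, FP %d, TN %d, FN %d\n",
    x$threshold, x$tp, x$fp, x$tn, x$fn
  ))
  invisible(x)
}

#' Thresholded classification metrics from confusion counts
#'
#' Computes accuracy, recall, precision, F-score and the Matthews
#' correlation coefficient.  A metric whose defining denominator is zero
#' is reported as `NA` (this is a value, not an error: e.g. precision and
#' F are undefined when no sample is predicted positive, and MCC is
#' undefined whenever a confusion-matrix marginal is empty).
#'
#' @param counts A [confusion_counts] object.
#' @return An object of class `metrics_report`: a list with fields
#'   `accuracy`, `precision`, `recall`, `f_score`, `mcc` and `counts`.
#' @examples
#' classification_metrics(confusion(c(1, 1, 0, 0), c(.9, .8, .3, .6), 0.5))
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  if (n < 1) stop_invalid("empty confusion matrix")
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  accuracy <- (tp + tn) / n
  recall <- frac(tp, tp + fn)
  precision <- frac(tp, tp + fp)
  f_score <- if (is.na(precision) || is.na(recall) ||
                 precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) NA_real_ else {
    (tp * tn - fp * fn) / mcc_den
  }
  structure(
    list(accuracy = accuracy, precision = precision, recall = recall,
         f_score = f_score, mcc = mcc, counts = counts),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.4f", v))
  cat(sprintf(
    "<metrics_report> t = %g | acc %s, prec %s, rec %s, F %s, MCC %s",
    x$counts$threshold, fmt(x$accuracy), fmt(x$precision),
    fmt(x$recall), fmt(x$f_score), fmt(x$mcc)
  ))
  if (!is.null(x$auprc)) cat(sprintf(", AUPRC %s", fmt(x$auprc)))
  cat("\n")
  invisible(x)
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision: samples are ranked by decreasing score
#' (ties grouped at equal scores) and
#' `AUPRC = sum over groups of precision * recall-increment`.
#' No trapezoidal interpolation is used, so the value is reproducible
#' bit-for-bit and is a pure rank statistic: any strictly increasing
#' transform of the scores leaves it exactly unchanged.
#'
#' @param labels 0/1 labels; both classes must be present.
#' @param scores Scores.
#' @return AUPRC in \[0, 1\].
#' @examples
#' auprc(c(1, 0, 1), c(0.9, 0.8, 0.7))  # 1 * 0.5 + 2/3 * 0.5
#' @export
auprc <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop_invalid("labels and scores must have equal length")
  }
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2) {
    stop_invalid("auprc needs both classes present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group ties: last index of each distinct score block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  cum_tp <- cumsum(y)[last]
  cum_n <- last
  npos <- sum(y)
  prec <- cum_tp / cum_n
  rec <- cum_tp / npos
  sum(prec * diff(c(0, rec)))
}

#' Reliability table and expected calibration error
#'
#' Partitions \[0, 1\] into `n_bins` equal-width bins
#' `((z-1)/Z, z/Z]`, z = 1..Z (a score of exactly 0 is assigned to the
#' first bin) and tabulates, per bin, the sample count, the mean
#' predicted probability and the empirical outcome frequency.  The
#' expected calibration error is the bin-count-weighted mean absolute
#' gap between the two, taken over non-empty bins (empty bins carry zero
#' weight):
#' `ECE = sum |C_z|/m * |freq(C_z) - mean_pred(C_z)|`.
#'
#' Two modes are available.  `"positive_fraction"` (default) bins the
#' positive-class score and compares it with the fraction of
#' disease-positive samples per bin -- the axes of a binary reliability
#' diagram.  `"confidence"` bins the confidence of the predicted class,
#' `max(s, 1 - s)`, and compares it with the fraction of correct
#' predictions under the rule "s >= 0.5 => positive".
#'
#' @param labels 0/1 labels.
#' @param scores Scores in \[0, 1\].
#' @param n_bins Number of bins Z >= 1 (default 10).
#' @param mode `"positive_fraction"` or `"confidence"`.
#' @return An object of class `reliability_table`: list with a `bins`
#'   data frame (`bin`, `lower`, `upper`, `n`, `mean_pred`, `frequency`),
#'   the `ece`, `n_bins`, `mode` and total count `m`.
#' @examples
#' reliability(c(1, 0, 1, 0), c(0.9, 0.2, 0.6, 0.4), n_bins = 2)
#' @export
reliability <- function(labels, scores, n_bins = 10,
                        mode = c("positive_fraction", "confidence")) {
  mode <- match.arg(mode)
  if (length(n_bins) != 1 || is.na(n_bins) || n_bins < 1) {
    stop_invalid("n_bins must be a positive integer")
  }
  if (length(labels) != length(scores)) {
    stop_invalid("labels and scores must have equal length")
  }
  if (!all(labels %in% c(0, 1))) stop_invalid("labels must be 0/1")
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop_invalid("scores must lie in [0, 1]")
  }
  Z <- as.integer(n_bins)
  m <- length(scores)
  if (mode == "positive_fraction") {
    value <- scores
    outcome <- as.numeric(labels == 1)
  } else {
    value <- pmax(scores, 1 - scores)
    outcome <- as.numeric((scores >= 0.5) == (labels == 1))
  }
  idx <- pmin(pmax(ceiling(value * Z), 1L), Z)
  bins <- data.frame(
    bin = seq_len(Z),
    lower = (seq_len(Z) - 1) / Z,
    upper = seq_len(Z) / Z,
    n = tabulate(idx, nbins = Z),
    mean_pred = NA_real_,
    frequency = NA_real_
  )
  occ <- bins$n > 0
  bins$mean_pred[occ] <- rowsum_by(value, idx, Z)[occ] / bins$n[occ]
  bins$frequency[occ] <- rowsum_by(outcome, idx, Z)[occ] / bins$n[occ]
  ece <- sum(bins$n[occ] / m * abs(bins$frequency[occ] - bins$mean_pred[occ]))
  structure(
    list(bins = bins, ece = ece, n_bins = Z, mode = mode, m = m),
    class = "reliability_table"
  )
}

#' @export
print.reliability_table <- function(x, ...) {
  cat(sprintf(
    "<reliability_table> %d bins (%s), m = %d, ECE = %.4f\n",
    x$n_bins, x$mode, x$m, x$ece
  ))
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Expected calibration error
#'
#' Shorthand for `reliability(...)$ece`.
#'
#' @inheritParams reliability
#' @return ECE in \[0, 1\].
#' @export
ece <- function(labels, scores, n_bins = 10,
                mode = c("positive_fraction", "confidence")) {
  reliability(labels, scores, n_bins = n_bins, mode = mode)$ece
}

#' Optimal classification threshold from the precision-recall curve
#'
#' Sweeps the candidate thresholds (every distinct observed score, plus
#' 0.5) under the rule "score >= threshold => positive", computes the
#' F-score at each, and returns the threshold with the largest F.  Ties
#' are broken toward the smallest threshold.  The result is exact and
#' deterministic; thresholds with undefined F are never selected.
#'
#' @param labels 0/1 labels; both classes must be present.
#' @param scores Scores in \[0, 1\].
#' @return An object of class `threshold_result`: list with
#'   `optimal_threshold`, `f_at_optimum` and the full `curve` data frame
#'   (`threshold`, `precision`, `recall`, `f_score`).
#' @examples
#' pr_optimal_threshold(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
#' @export
pr_optimal_threshold <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop_invalid("labels and scores must have equal length")
  }
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2) {
    stop_invalid("threshold selection needs both classes present")
  }
  cand <- sort(unique(c(scores, 0.5)))
  npos <- sum(labels == 1)
  nneg <- length(labels) - npos
  ord <- order(scores)
  s <- scores[ord]
  y <- labels[ord]
  pos_upto <- cumsum(y)       # positives with score <= s[i]
  neg_upto <- cumsum(1 - y)
  # number of samples with score strictly below each candidate threshold
  n_lt <- findInterval(cand, s, left.open = TRUE)
  pos_lt <- ifelse(n_lt > 0, pos_upto[pmax(n_lt, 1)], 0)
  neg_lt <- ifelse(n_lt > 0, neg_upto[pmax(n_lt, 1)], 0)
  tp <- npos - pos_lt         # predicted positive by the >= rule
  fp <- nneg - neg_lt
  precision <- ifelse(tp + fp == 0, NA_real_, tp / (tp + fp))
  recall <- tp / npos
  f <- ifelse(is.na(precision) | precision + recall == 0,
              NA_real_, 2 * precision * recall / (precision + recall))
  curve <- data.frame(threshold = cand, precision = precision,
                      recall = recall, f_score = f)
  fcmp <- ifelse(is.na(f), -Inf, f)
  best <- which.max(fcmp)  # which.max returns the first (smallest t) maximum
  structure(
    list(optimal_threshold = cand[best], f_at_optimum = f[best],
         curve = curve),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> optimal threshold %.4f (F = %.4f, %d candidates)\n",
    x$optimal_threshold, x$f_at_optimum, nrow(x$curve)
  ))
  invisible(x)
}

#' Full metrics report for scores at a threshold
#'
#' Convenience wrapper producing the complete per-cell report used by the
#' experiment pipeline: confusion counts, thresholded metrics, AUPRC and
#' (optionally) Wilson 95% intervals for MCC, accuracy and F.
#'
#' @param labels 0/1 labels.
#' @param scores Scores in \[0, 1\].
#' @param threshold Decision threshold.
#' @param ci Attach Wilson intervals (default TRUE).
#' @param level Confidence level.
#' @return A `metrics_report` with `auprc` and, when `ci`, a `ci` list of
#'   [wilson_interval] objects keyed by metric.
#' @export
metrics_report <- function(labels, scores, threshold, ci = TRUE,
                           level = 0.95) {
  rep <- classification_metrics(confusion(labels, scores, threshold))
  rep$auprc <- if (length(unique(labels)) < 2) NA_real_ else {
    auprc(labels, scores)
  }
  if (ci) {
    n <- length(labels)
    rep$ci <- list(
      accuracy = metric_interval(rep$accuracy, "accuracy", n, level),
      f = metric_interval(rep$f_score, "f", n, level),
      mcc = metric_interval(rep$mcc, "mcc", n, level)
    )
  }
  rep
}
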