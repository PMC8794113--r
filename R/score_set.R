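#' Labeled classifier scores for one data split
#'
#' A `score_set` bundles binary labels (1 = disease-positive) with the
#' classifier's positive-class probabilities for one split of a study,
#' together with provenance metadata (imbalance ratio, distortion family
#' and, for synthetic data, the latent calibrated posterior each label was
#' drawn from).  It is the common currency passed between the synthetic
#' generator, the calibrators and the evaluation metrics.
#'
#' @param ids Character or integer sample identifiers.
#' @param labels Integer vector in \{0, 1\}; 1 denotes the disease-positive
#'   (abnormal) class.
#' @param scores Numeric vector of positive-class probabilities in
#'   \[0, 1\].
#' @param true_probs Optional numeric vector of latent perfectly
#'   calibrated posteriors (synthetic data only).
#' @param meta Optional list of provenance metadata, stored as an
#'   attribute.
#'
#' @return A data frame of class `score_set` with columns `id`, `label`,
#'   `score` and optionally `true_prob`.
#' @examples
#' ss <- score_set(1:4, c(0, 1, 0, 1), c(0.2, 0.8, 0.4, 0.9))
#' summary(ss$score)
#' @export
score_set <- function(ids, labels, scores, true_probs = NULL, meta = list()) {
  n <- length(labels)
  if (length(ids) != n || length(scores) != n) {
    stop_invalid("ids, labels and scores must have equal length")
  }
  if (!all(labels %in% c(0, 1))) {
    stop_invalid("labels must be 0 (negative) or 1 (disease-positive)")
  }
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop_invalid("scores must lie in [0, 1] and contain no missing values")
  }
  df <- data.frame(
    id = as.character(ids),
    label = as.integer(labels),
    score = as.numeric(scores),
    stringsAsFactors = FALSE
  )
  if (!is.null(true_probs)) {
    if (length(true_probs) != n) {
      stop_invalid("true_probs must match the number of samples")
    }
    if (anyNA(true_probs) || any(true_probs < 0 | true_probs > 1)) {
      stop_invalid("true_probs must lie in [0, 1]")
    }
    df$true_prob <- as.numeric(true_probs)
  }
  structure(df, meta = meta, class = c("score_set", "data.frame"))
}

#' @export
print.score_set <- function(x, ...) {
  n <- nrow(x)
  npos <- sum(x$label == 1)
  cat(sprintf(
    "<score_set> %d samples (%d positive, %d negative)\n",
    n, npos, n - npos
  ))
  meta <- attr(x, "meta")
  if (length(meta)) {
    keys <- vapply(names(meta), function(k) {
      v <- meta[[k]]
      if (is.atomic(v) && length(v) == 1) paste0(k, "=", format(v)) else k
    }, character(1))
    cat("  meta:", paste(keys, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a delimited score file
#'
#' Parses the package's score-file dialect: a comma-delimited UTF-8 file
#' with header `id,label,score` and an optional fourth column
#' `true_prob`.  Labels must be 0/1 and scores must be probabilities;
#' malformed rows are rejected with the offending line number.
#'
#' @param path Path to the file.
#' @return A [score_set].
#' @seealso [write_scores()]
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop_invalid("score file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  required <- c("id", "label", "score")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop_invalid(
      "score file ", path, " is missing required column(s): ",
      paste(missing, collapse = ", ")
    )
  }
  # +1 for the header: report 1-based physical line numbers.
  line_of <- function(i) i + 1L
  lab <- suppressWarnings(as.numeric(raw$label))
  bad <- which(is.na(lab) | !(lab %in% c(0, 1)))
  if (length(bad)) {
    stop_invalid(
      "invalid label ", dQuote(raw$label[bad[1]]), " at line ",
      line_of(bad[1]), " of ", path, " (must be 0 or 1)"
    )
  }
  sc <- suppressWarnings(as.numeric(raw$score))
  bad <- which(is.na(sc) | sc < 0 | sc > 1)
  if (length(bad)) {
    stop_invalid(
      "invalid score ", dQuote(raw$score[bad[1]]), " at line ",
      line_of(bad[1]), " of ", path, " (must be a number in [0, 1])"
    )
  }
  tp <- NULL
  if ("true_prob" %in% names(raw)) {
    tp <- suppressWarnings(as.numeric(raw$true_prob))
    bad <- which(is.na(tp) | tp < 0 | tp > 1)
    if (length(bad)) {
      stop_invalid(
        "invalid true_prob at line ", line_of(bad[1]), " of ", path
      )
    }
  }
  score_set(raw$id, as.integer(lab), sc, true_probs = tp,
            meta = list(source = path))
}

#' Write a score set to a delimited file
#'
#' Inverse of [read_scores()].  Numbers are written with 17 significant
#' digits so that a write/read round trip reproduces the scores exactly.
#'
#' @param x A [score_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(x, path) {
  stopifnot(inherits(x, "score_set"))
  cols <- c("id", "label", "score")
  out <- data.frame(
    id = x$id,
    label = x$label,
    score = format_full(x$score),
    stringsAsFactors = FALSE
  )
  if (!is.null(x$true_prob)) {
    out$true_prob <- format_full(x$true_prob)
    cols <- c(cols, "true_prob")
  }
  utils::write.csv(out[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
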