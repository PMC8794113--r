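#' Specification of an imbalance-controlled synthetic dataset
#'
#' Describes one class-imbalance condition of the study design: a
#' calibration-fit partition with `n_negative` disease-negative samples
#' and `round(ratio * n_negative)` disease-positive samples (rounding is
#' round-half-to-even, R's default), plus a test partition whose class
#' counts are fixed independently of `ratio` so that test-set difficulty
#' is held constant across the imbalance sweep.
#'
#' The defaults mirror a chest X-ray style design: 226 negatives in the
#' fit partition and a balanced 100/100 test partition.
#'
#' @param n_negative Number of disease-negative samples in the
#'   calibration-fit partition (>= 1).
#' @param ratio Positive-to-negative proportion in (0, 1].
#' @param test_negative,test_positive Class counts of the test partition.
#' @param seed Integer RNG seed for this condition.
#' @return An object of class `dataset_spec`.
#' @examples
#' dataset_spec(n_negative = 226, ratio = 0.2)
#' @export
dataset_spec <- function(n_negative = 226, ratio = 1,
                         test_negative = 100, test_positive = 100,
                         seed = 1L) {
  if (length(n_negative) != 1 || is.na(n_negative) || n_negative < 1) {
    stop_invalid("n_negative must be a single integer >= 1")
  }
  if (length(ratio) != 1 || is.na(ratio) || ratio <= 0 || ratio > 1) {
    stop_invalid("ratio must lie in (0, 1]")
  }
  n_positive <- round(ratio * n_negative)
  if (n_positive < 1) {
    stop_invalid(
      "ratio ", ratio, " with n_negative ", n_negative,
      " yields no positive samples"
    )
  }
  if (test_negative < 1 || test_positive < 1) {
    stop_invalid("test partition class counts must be >= 1")
  }
  structure(
    list(
      n_negative = as.integer(n_negative),
      ratio = as.numeric(ratio),
      n_positive = as.integer(n_positive),
      test_negative = as.integer(test_negative),
      test_positive = as.integer(test_positive),
      seed = as.integer(seed)
    ),
    class = "dataset_spec"
  )
}

#' @export
print.dataset_spec <- function(x, ...) {
  cat(sprintf(
    "<dataset_spec> fit %d/%d (neg/pos, ratio %.2f), test %d/%d, seed %d\n",
    x$n_negative, x$n_positive, x$ratio,
    x$test_negative, x$test_positive, x$seed
  ))
  invisible(x)
}

#' Specification of a parametric miscalibration distortion
#'
#' A distortion is a strictly increasing map applied to the latent
#' calibrated posteriors to emulate a miscalibrated classifier.  All
#' families act on the log-odds of the posterior and return scores in
#' (0, 1):
#'
#' * `identity`: scores equal the posteriors (a perfectly calibrated
#'   classifier).
#' * `platt_family`: `score = plogis((qlogis(p) - alpha) / beta)`, the
#'   inverse of a two-parameter logistic (Platt) calibration map, so that
#'   fitting Platt scaling to the output recovers `(alpha, beta)`.
#'   `beta < 1` yields overconfident scores, `beta > 1` underconfident.
#' * `beta_family`: the inverse of the three-parameter beta calibration
#'   map `p = plogis(c + a*log(z) - b*log(1 - z))` with `a, b > 0`.
#' * `majority_collapse`: a downward log-odds shift
#'   `score = plogis(qlogis(p) - delta)` emulating a classifier so biased
#'   toward the majority (negative) class that every disease-positive
#'   sample scores below 0.5.  With `delta = NULL` the shift is chosen
#'   from the generated sample so the collapse holds by construction.
#'
#' @param family One of `"identity"`, `"beta_family"`, `"platt_family"`,
#'   `"majority_collapse"`.
#' @param params Named list of family parameters (see Details).  Defaults:
#'   `platt_family` uses `alpha = -2, beta = 4`; `beta_family` uses
#'   `a = 2, b = 1, c = 0.5`; `majority_collapse` uses `delta = NULL`
#'   (automatic).
#' @param separability Latent class-separation effect size `d >= 0` used
#'   by [generate_latent_scores()]; `d = 2` gives a moderately strong
#'   classifier (balanced accuracy about 0.84).
#' @return An object of class `distortion_spec`.
#' @examples
#' distortion_spec("platt_family", list(alpha = -2, beta = 4))
#' distortion_spec("identity")
#' @export
distortion_spec <- function(family = c("identity", "beta_family",
                                       "platt_family", "majority_collapse"),
                            params = NULL, separability = 2) {
  family <- match.arg(family)
  if (length(separability) != 1 || is.na(separability) || separability < 0) {
    stop_invalid("separability must be a single number >= 0")
  }
  defaults <- switch(family,
    identity = list(),
    platt_family = list(alpha = -2, beta = 4),
    beta_family = list(a = 2, b = 1, c = 0.5),
    majority_collapse = list(delta = NULL)
  )
  if (is.null(params)) params <- list()
  if (family == "identity" && length(params)) {
    stop_invalid("the identity family takes no parameters")
  }
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop_invalid(
      "unknown parameter(s) for family ", family, ": ",
      paste(unknown, collapse = ", ")
    )
  }
  p <- utils::modifyList(defaults, params)
  if (family == "platt_family" && (!is.finite(p$beta) || p$beta <= 0)) {
    stop_invalid("platt_family requires beta > 0 for an invertible map")
  }
  if (family == "beta_family" && (p$a <= 0 || p$b <= 0)) {
    stop_invalid("beta_family requires a > 0 and b > 0 for an invertible map")
  }
  if (family == "majority_collapse" && !is.null(p$delta) && p$delta <= 0) {
    stop_invalid("majority_collapse requires delta > 0")
  }
  structure(
    list(family = family, params = p, separability = as.numeric(separability)),
    class = "distortion_spec"
  )
}

#' @export
print.distortion_spec <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste(names(x$params),
          vapply(x$params, function(v) {
            if (is.null(v)) "auto" else format(v)
          }, character(1)),
          sep = "=", collapse = ", ")
  } else "none"
  cat(sprintf(
    "<distortion_spec> %s (params: %s), separability d = %g\n",
    x$family, ps, x$separability
  ))
  invisible(x)
}

#' Generate an imbalance-controlled label vector
#'
#' Returns `spec$n_negative` zeros and `round(spec$ratio * spec$n_negative)`
#' ones in randomized order under `spec$seed`.  Rounding of the positive
#' count is round-half-to-even (R's `round`).
#'
#' @param spec A [dataset_spec].
#' @return Integer vector of 0/1 labels.
#' @examples
#' table(make_imbalanced_labels(dataset_spec(1000, 0.2)))
#' @export
make_imbalanced_labels <- function(spec) {
  if (!inherits(spec, "dataset_spec")) {
    stop_invalid("spec must be a dataset_spec")
  }
  gen_labels(spec$n_negative, spec$ratio, spec$seed)
}

gen_labels <- function(n_negative, ratio, seed) {
  n_pos <- round(ratio * n_negative)
  labels <- c(rep(0L, n_negative), rep(1L, n_pos))
  with_seed(seed, sample(labels))
}

#' Generate latent perfectly calibrated posteriors
#'
#' For each sample a latent feature is drawn from a unit-variance normal
#' with class-conditional mean `+d/2` (positive) or `-d/2` (negative).
#' The returned probability is the exact Bayes posterior of this
#' generative model,
#' `p = plogis(d * x + qlogis(prevalence))`,
#' so the scores are calibrated by construction: among samples with
#' posterior near `p`, a fraction `p` is positive.  With `d = 0` every
#' posterior equals the prevalence.
#'
#' @param labels 0/1 label vector containing both classes.
#' @param separability Effect size `d >= 0` separating the class means.
#' @param prevalence Positive-class prior; must equal the positive
#'   fraction of `labels` (the default).
#' @param seed Integer RNG seed.
#' @return Numeric vector of calibrated posterior probabilities.
#' @export
generate_latent_scores <- function(labels, separability,
                                   prevalence = mean(labels == 1),
                                   seed = 1L) {
  if (separability < 0) stop_invalid("separability must be >= 0")
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2) {
    stop_invalid("labels must contain both classes")
  }
  pi_hat <- mean(labels == 1)
  if (abs(prevalence - pi_hat) > 1e-8) {
    stop_invalid(
      "prevalence (", format(prevalence),
      ") must equal the positive fraction of labels (", format(pi_hat), ")"
    )
  }
  d <- separability
  with_seed(seed, {
    x <- stats::rnorm(length(labels),
                      mean = ifelse(labels == 1, d / 2, -d / 2), sd = 1)
    stats::plogis(d * x + stats::qlogis(prevalence))
  })
}

#' Apply a miscalibration distortion to calibrated posteriors
#'
#' Maps latent calibrated posteriors through the strictly increasing
#' distortion described by `distortion` (see [distortion_spec()]).
#' Posteriors are clipped to `[1e-6, 1 - 1e-6]` before any log-odds
#' transform.  The rank order of the output equals the rank order of the
#' input for every family.
#'
#' For `majority_collapse` with `delta = NULL`, `labels` must be supplied:
#' the shift is set to push the largest positive-class score to 0.45.
#' When `delta` is given and `labels` are available, the collapse
#' condition (all positive-class scores < 0.5) is verified and a
#' violation is an error.
#'
#' @param true_probs Numeric vector of probabilities.
#' @param distortion A [distortion_spec].
#' @param labels Optional 0/1 labels, required to auto-select or validate
#'   the `majority_collapse` shift.
#' @return Numeric vector of distorted scores in (0, 1).  For
#'   `majority_collapse` the shift actually used is attached as attribute
#'   `"delta"`.
#' @export
distort_scores <- function(true_probs, distortion, labels = NULL) {
  if (!inherits(distortion, "distortion_spec")) {
    stop_invalid("distortion must be a distortion_spec")
  }
  p <- clip_prob(true_probs)
  u <- stats::qlogis(p)
  pars <- distortion$params
  # Distorted scores are clamped to [eps, 1 - eps]: mathematically every
  # family maps into (0, 1), but a steep distortion can saturate to
  # exactly 0 or 1 in double precision, which would make the scores'
  # log-odds infinite downstream.
  switch(distortion$family,
    identity = true_probs,
    platt_family = clip_prob(stats::plogis((u - pars$alpha) / pars$beta)),
    beta_family = invert_beta_map(u, pars$a, pars$b, pars$c),
    majority_collapse = {
      delta <- pars$delta
      if (is.null(delta)) {
        if (is.null(labels)) {
          stop_invalid(
            "majority_collapse with delta = NULL needs labels to choose the shift"
          )
        }
        if (!any(labels == 1)) {
          stop_invalid("majority_collapse needs at least one positive label")
        }
        # push the most confident positive down to score 0.45
        delta <- max(u[labels == 1]) - stats::qlogis(0.45)
        delta <- max(delta, .EPS)
      }
      out <- clip_prob(stats::plogis(u - delta))
      if (!is.null(labels) && any(labels == 1) &&
          max(out[labels == 1]) >= 0.5) {
        stop_invalid(
          "majority_collapse delta = ", format(delta),
          " does not push all positive-class scores below 0.5"
        )
      }
      attr(out, "delta") <- delta
      out
    }
  )
}

# Solve a*log(z) - b*log(1-z) + c = u for z by monotone bisection
# (vectorized; 60 halvings give ~1e-18 interval width on (0,1)).
invert_beta_map <- function(u, a, b, c) {
  lo <- rep(.EPS, length(u))
  hi <- rep(1 - .EPS, length(u))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    v <- a * log(mid) - b * log1p(-mid) + c
    below <- v < u
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Generate one synthetic score set
#'
#' Convenience wrapper chaining label generation, latent posterior
#' simulation and distortion into a [score_set] with full provenance
#' metadata.  Sub-seeds for the three stages are derived
#' deterministically from `seed`.
#'
#' @param n_negative,ratio Class counts as in [dataset_spec()].
#' @param distortion A [distortion_spec].
#' @param seed Integer seed.
#' @param id_prefix Prefix for sample identifiers.
#' @return A [score_set] with `true_prob` column.
#' @examples
#' ss <- make_score_set(200, 0.5, distortion_spec("identity"), seed = 7)
#' table(ss$label)
#' @export
make_score_set <- function(n_negative, ratio, distortion, seed,
                           id_prefix = "s") {
  labels <- gen_labels(n_negative, ratio, derive_seed(seed, 1))
  true_probs <- generate_latent_scores(
    labels, distortion$separability, seed = derive_seed(seed, 2)
  )
  scores <- distort_scores(true_probs, distortion, labels = labels)
  delta <- attr(scores, "delta")
  meta <- list(
    n_negative = n_negative, ratio = ratio,
    family = distortion$family, separability = distortion$separability,
    params = distortion$params, seed = seed
  )
  if (!is.null(delta)) meta$delta <- delta
  score_set(
    paste0(id_prefix, seq_along(labels)), labels, as.numeric(scores),
    true_probs = true_probs, meta = meta
  )
}

#' Build the imbalance sweep of calibration/test score-set pairs
#'
#' For each requested positive:negative ratio, generates a
#' calibration-fit [score_set] at that imbalance and a test [score_set].
#' By default the test partition is the same fixed balanced design for
#' every ratio (`fixed_test = TRUE`), so only the fitting partition's
#' positive count varies across the sweep; with `fixed_test = FALSE` the
#' test partition inherits the ratio.
#'
#' Each (ratio, split) cell draws its own seed from `template$seed` via a
#' documented counter scheme, so any single cell can be regenerated in
#' isolation.
#'
#' @param template A [dataset_spec] providing `n_negative`, the test
#'   partition sizes and the master seed.
#' @param ratios Numeric vector of ratios in (0, 1].
#' @param distortion A [distortion_spec] applied to both splits.
#' @param fixed_test Keep the test partition balanced at the template's
#'   test sizes for every ratio (default), or let it follow `ratio`.
#' @return Named list (one element per ratio, names like `"0.2"`), each a
#'   list with elements `cal` and `test`.
#' @examples
#' sets <- build_study_sets(
#'   dataset_spec(226, seed = 11), ratios = c(0.2, 1),
#'   distortion = distortion_spec("identity")
#' )
#' names(sets)
#' @export
build_study_sets <- function(template, ratios, distortion,
                             fixed_test = TRUE) {
  if (!inherits(template, "dataset_spec")) {
    stop_invalid("template must be a dataset_spec")
  }
  if (!length(ratios) || any(ratios <= 0 | ratios > 1)) {
    stop_invalid("ratios must be a non-empty subset of (0, 1]")
  }
  out <- vector("list", length(ratios))
  names(out) <- format(ratios)
  for (i in seq_along(ratios)) {
    r <- ratios[i]
    # counter scheme: cell 10*i + 1 -> calibration split, 10*i + 2 -> test
    cal <- make_score_set(
      template$n_negative, r, distortion,
      seed = derive_seed(template$seed, 10 * i + 1), id_prefix = "cal"
    )
    if (fixed_test) {
      n_neg <- template$test_negative
      test_ratio <- template$test_positive / template$test_negative
      if (round(test_ratio * n_neg) != template$test_positive) {
        stop_invalid("test partition sizes are not representable as a ratio")
      }
    } else {
      n_neg <- template$test_negative
      test_ratio <- r
    }
    test <- make_score_set(
      n_neg, test_ratio, distortion,
      seed = derive_seed(template$seed, 10 * i + 2), id_prefix = "test"
    )
    attr(cal, "meta")$split <- "calibration"
    attr(test, "meta")$split <- "test"
    out[[i]] <- list(cal = cal, test = test)
  }
  out
}
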