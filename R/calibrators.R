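#' Construct a calibration map object
#'
#' A `calibration_map` is a fitted, monotone-intended map from a raw
#' classifier score in \[0, 1\] to a calibrated probability.  Maps are
#' produced by [fit_platt()], [fit_beta()], [fit_spline()] or
#' [identity_map()], and applied with [apply_map()] or `predict()`.
#'
#' All parametric families act on the log-odds `u = qlogis(score)` of the
#' (clipped) input score: a probability-valued classifier output carries
#' its information on the log-odds scale, and both the Platt and the beta
#' family are logistic-linear in transforms of `u`.
#'
#' @param method One of `"identity"`, `"platt"`, `"beta"`, `"spline"`.
#' @param params Named list of fitted parameters for the method.
#' @param fit_n Number of samples the map was fitted on.
#' @return An object of class `calibration_map`.
#' @export
calibration_map <- function(method, params = list(), fit_n = NA_integer_) {
  method <- match.arg(method, c("identity", "platt", "beta", "spline"))
  structure(
    list(method = method, params = params, fit_n = as.integer(fit_n)),
    class = "calibration_map"
  )
}

#' @rdname calibration_map
#' @export
identity_map <- function() calibration_map("identity")

#' @export
print.calibration_map <- function(x, ...) {
  desc <- switch(x$method,
    identity = "identity (uncalibrated passthrough)",
    platt = sprintf("Platt: alpha = %.4f, beta = %.4f",
                    x$params$alpha, x$params$beta),
    beta = sprintf("beta: a = %.4f, b = %.4f, c = %.4f",
                   x$params$a, x$params$b, x$params$c),
    spline = sprintf("spline: %d knots, lambda = %.4g",
                     length(x$params$knots), x$params$lambda)
  )
  cat("<calibration_map>", desc)
  if (!is.na(x$fit_n)) cat(sprintf(" [fit on n = %d]", x$fit_n))
  cat("\n")
  invisible(x)
}

# ---- Platt scaling --------------------------------------------------------

#' Fit a two-parameter Platt calibration map
#'
#' Maximizes the Bernoulli likelihood of
#' `p = plogis(alpha + beta * qlogis(z))`
#' over the intercept `alpha` and slope `beta`, using Platt's smoothed
#' targets `(N+ + 1)/(N+ + 2)` and `1/(N- + 2)` in place of the hard 1/0
#' labels (this keeps the parameters finite under perfect separation).
#' Optimization is damped Newton with tolerance 1e-8 and at most 100
#' iterations; the fit is deterministic.
#'
#' `(alpha, beta) = (0, 1)` is the identity map.  A fitted `beta <= 0`
#' indicates negatively oriented scores and triggers a warning, not an
#' error.  If the scores carry no signal (all identical), `beta` is fixed
#' at 0 and the map returns the smoothed prevalence everywhere.
#'
#' @param scores Raw positive-class probabilities in \[0, 1\].
#' @param labels 0/1 labels; both classes must be present.
#' @return A [calibration_map] with `method = "platt"` and parameters
#'   `alpha`, `beta`.
#' @examples
#' set.seed(1)
#' p <- runif(500)
#' y <- rbinom(500, 1, p)
#' fit_platt(plogis((qlogis(p) + 2) / 4), y)
#' @export
fit_platt <- function(scores, labels) {
  check_fit_input(scores, labels, min_n = 2)
  u <- stats::qlogis(clip_prob(scores))
  t <- platt_targets(labels)
  if (stats::sd(u) < 1e-12) {
    alpha <- stats::qlogis(mean(t))
    return(calibration_map("platt", list(alpha = alpha, beta = 0),
                           fit_n = length(labels)))
  }
  fit <- newton_logistic(cbind(1, u), t, start = c(0, 1))
  if (!fit$converged) {
    stop_invalid(
      "Platt fit did not converge after ", fit$iterations,
      " iterations (coefficients ", paste(format(fit$coef), collapse = ", "), ")"
    )
  }
  if (fit$coef[2] <= 0) {
    warning("fitted Platt slope beta <= 0: scores look negatively oriented",
            call. = FALSE)
  }
  calibration_map("platt",
                  list(alpha = fit$coef[1], beta = fit$coef[2]),
                  fit_n = length(labels))
}

#' Apply a Platt calibration map
#'
#' Elementwise `plogis(alpha + beta * qlogis(clip(z)))`; strictly
#' increasing when `beta > 0`.
#'
#' @param params A [calibration_map] of method `"platt"`, or a list with
#'   elements `alpha` and `beta`.
#' @param scores Scores in \[0, 1\].
#' @return Calibrated probabilities.
#' @export
apply_platt <- function(params, scores) {
  p <- map_params(params, "platt")
  if (!length(scores)) return(numeric(0))
  stats::plogis(p$alpha + p$beta * stats::qlogis(clip_prob(scores)))
}

# ---- Beta calibration -----------------------------------------------------

#' Fit a three-parameter beta calibration map
#'
#' Fits the logistic-likelihood regression of the labels on the features
#' `log(z)` and `-log(1 - z)`, giving the beta-calibration map
#' `p = 1 / (1 + exp(-c) * (1 - z)^b / z^a)`
#' with slope parameters `a, b` and intercept `c`.  Monotonicity requires
#' `a, b >= 0`: if an unconstrained slope comes out negative it is set to
#' 0 and the model refitted without that feature (drop-and-refit, the
#' reference behavior for this family).  `(a, b, c) = (1, 1, 0)` is the
#' identity, so beta calibration leaves an already calibrated classifier
#' essentially unchanged.
#'
#' Hard 0/1 targets are used; if the unconstrained fit fails to converge
#' (e.g. perfectly separated scores) the fit is retried with Platt's
#' smoothed targets.
#'
#' @inheritParams fit_platt
#' @return A [calibration_map] with `method = "beta"` and parameters
#'   `a`, `b`, `c`.
#' @export
fit_beta <- function(scores, labels) {
  check_fit_input(scores, labels, min_n = 2)
  z <- clip_prob(scores)
  X <- cbind(1, log(z), -log1p(-z))
  keep <- c(TRUE, TRUE)  # (a, b) features currently in the model
  t_hard <- as.numeric(labels == 1)
  repeat {
    Xk <- X[, c(TRUE, keep), drop = FALSE]
    fit <- newton_logistic(Xk, t_hard)
    if (!fit$converged) {
      fit <- newton_logistic(Xk, platt_targets(labels))
      if (!fit$converged) {
        stop_invalid("beta calibration fit did not converge")
      }
    }
    ab <- numeric(2)
    ab[keep] <- fit$coef[-1]
    if (any(ab < 0)) {
      keep <- keep & (ab >= 0)
      if (!any(keep)) {
        # intercept-only model: constant smoothed prevalence
        fit0 <- newton_logistic(X[, 1, drop = FALSE], platt_targets(labels))
        return(calibration_map("beta",
                               list(a = 0, b = 0, c = fit0$coef[1]),
                               fit_n = length(labels)))
      }
      next
    }
    return(calibration_map("beta",
                           list(a = ab[1], b = ab[2], c = fit$coef[1]),
                           fit_n = length(labels)))
  }
}

#' Apply a beta calibration map
#'
#' Elementwise `1 / (1 + exp(-c) * (1 - z)^b / z^a)` on clipped scores;
#' non-decreasing whenever `a, b >= 0`.
#'
#' @param params A [calibration_map] of method `"beta"`, or a list with
#'   elements `a`, `b`, `c`.
#' @param scores Scores in \[0, 1\].
#' @return Calibrated probabilities.
#' @export
apply_beta <- function(params, scores) {
  p <- map_params(params, "beta")
  if (!length(scores)) return(numeric(0))
  z <- clip_prob(scores)
  stats::plogis(p$c + p$a * log(z) - p$b * log1p(-z))
}

# ---- Spline calibration ---------------------------------------------------

#' Default smoothing-parameter grid for spline calibration
#'
#' Twenty log-spaced values between 1e-4 and 1e2.
#' @return Numeric vector.
#' @export
default_lambda_grid <- function() 10^seq(-4, 2, length.out = 20)

#' Fit a cubic smoothing-spline calibration map
#'
#' Fits a natural cubic smoothing spline `f` on the log-odds scale: with
#' `u = qlogis(clip(z))`, the calibrated probability is `plogis(f(u))`
#' and `f` maximizes the penalized Bernoulli log-likelihood
#' `sum(y * f - log(1 + exp(f))) - lambda * integral(f'')^2`.
#' The basis is the natural cubic ("cr") basis of \pkg{mgcv} with
#' `min(n, 40)` knots at quantiles of `u`.  The nuisance parameter
#' `lambda` is selected from `lambda_grid` by the highest held-out
#' log-likelihood under a fixed seed-controlled 5-fold split, then the
#' spline is refitted on all data at the selected value.
#'
#' For speed at large n, the fold fits of the grid search aggregate the
#' data over `min(n, 1000)` quantile bins of `u` (covariate discretization
#' as in `mgcv::bam(discrete = TRUE)`); the final fit at the selected
#' `lambda` uses the raw, unbinned data.
#'
#' The fitted map is intended to be monotone but monotonicity is not
#' enforced; [map_monotone()] reports it.
#'
#' @inheritParams fit_platt
#' @param lambda_grid Candidate smoothing parameters
#'   (default [default_lambda_grid()]).
#' @param nfolds Number of cross-validation folds (default 5).
#' @param seed Seed for the fold split; the fit is deterministic given it.
#' @return A [calibration_map] with `method = "spline"`; parameters are
#'   the knot positions (log-odds and score scale), the spline
#'   coefficients, the selected `lambda` and the selection trace
#'   (`lambda_grid`, held-out log-likelihoods).
#' @export
fit_spline <- function(scores, labels, lambda_grid = default_lambda_grid(),
                       nfolds = 5, seed = 1L) {
  check_fit_input(scores, labels, min_n = 10)
  if (!length(lambda_grid) || any(lambda_grid <= 0)) {
    stop_invalid("lambda_grid must contain positive values")
  }
  u <- stats::qlogis(clip_prob(scores))
  if (length(unique(u)) < 4) {
    stop_invalid("spline calibration needs at least 4 distinct score values")
  }
  n <- length(u)
  y <- as.numeric(labels == 1)
  K <- min(n, 40)
  knots_u <- unique(stats::quantile(u, probs = seq(0, 1, length.out = K),
                                    names = FALSE, type = 7))
  K <- length(knots_u)
  basis <- spline_basis(knots_u)
  X <- spline_design(basis, u)
  S <- basis$S

  fold <- with_seed(seed, sample(rep(seq_len(nfolds), length.out = n)))

  # discretized data for the lambda-grid search
  nbin <- min(n, 1000)
  brk <- unique(stats::quantile(u, probs = seq(0, 1, length.out = nbin + 1),
                                names = FALSE, type = 7))
  bin <- findInterval(u, brk, rightmost.closed = TRUE, all.inside = TRUE)
  ubin <- tapply(u, bin, mean)
  Xbin <- spline_design(basis, as.numeric(ubin))
  bin_index <- as.integer(factor(bin))

  ord <- order(lambda_grid, decreasing = TRUE)  # warm start smooth -> wiggly
  cvll <- numeric(length(lambda_grid))
  for (f in seq_len(nfolds)) {
    tr <- fold != f
    cnt <- tabulate(bin_index[tr], nbins = nrow(Xbin))
    ysum <- rowsum_by(y[tr], bin_index[tr], nrow(Xbin))
    occ <- cnt > 0
    tbar <- ysum[occ] / cnt[occ]
    Xf <- Xbin[occ, , drop = FALSE]
    wf <- cnt[occ]
    Xte <- X[!tr, , drop = FALSE]
    yte <- y[!tr]
    b <- rep(0, K)
    for (li in ord) {
      fit <- newton_logistic(Xf, tbar, w = wf, penalty = S,
                             lambda = lambda_grid[li], start = b,
                             tol = 1e-8, maxit = 60L)
      b <- fit$coef
      cvll[li] <- cvll[li] + bernoulli_loglik(drop(Xte %*% b), yte)
    }
  }
  best <- which.max(cvll)
  lambda <- lambda_grid[best]
  final <- newton_logistic(X, y, penalty = S, lambda = lambda,
                           tol = 1e-9, maxit = 100L)
  if (!final$converged) {
    stop_invalid("spline calibration fit did not converge at lambda = ",
                 format(lambda))
  }
  calibration_map("spline", list(
    knots = knots_u,
    knots_score = stats::plogis(knots_u),
    coefficients = final$coef,
    lambda = as.numeric(lambda),
    selection_trace = data.frame(lambda = as.numeric(lambda_grid),
                                 cv_loglik = cvll),
    nfolds = as.integer(nfolds),
    seed = as.integer(seed)
  ), fit_n = n)
}

# Natural cubic regression spline basis (mgcv "cr") on stored knots, with
# its integrated-squared-second-derivative penalty.  The coefficients are
# the function values at the knots; evaluation beyond the boundary knots
# extrapolates linearly.
spline_basis <- function(knots_u) {
  K <- length(knots_u)
  sm <- mgcv::smoothCon(
    mgcv::s(u, bs = "cr", k = K),
    data = data.frame(u = knots_u),
    knots = list(u = knots_u),
    absorb.cons = FALSE
  )[[1]]
  list(sm = sm, S = sm$S[[1]])
}

spline_design <- function(basis, u) {
  mgcv::PredictMat(basis$sm, data.frame(u = u))
}

rowsum_by <- function(x, index, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(x, index)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Apply a spline calibration map
#'
#' Evaluates the fitted spline on the log-odds of the clipped scores and
#' returns `plogis(f(u))`, clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param params A [calibration_map] of method `"spline"`.
#' @param scores Scores in \[0, 1\].
#' @return Calibrated probabilities.
#' @export
apply_spline <- function(params, scores) {
  p <- map_params(params, "spline")
  if (!length(scores)) return(numeric(0))
  basis <- spline_basis(p$knots)
  u <- stats::qlogis(clip_prob(scores))
  eta <- drop(spline_design(basis, u) %*% p$coefficients)
  clip_prob(stats::plogis(eta))
}

# ---- Generic application and diagnostics ---------------------------------

#' Apply a fitted calibration map to scores
#'
#' Dispatches on the map's method; the identity method is an exact
#' passthrough.  Outputs are clipped to \[0, 1\] and an empty input
#' yields an empty output.
#'
#' @param map A [calibration_map].
#' @param scores Scores in \[0, 1\].
#' @return Calibrated probabilities.
#' @examples
#' apply_map(identity_map(), c(0.1, 0.9))
#' @export
apply_map <- function(map, scores) {
  if (!inherits(map, "calibration_map")) {
    stop_invalid("map must be a calibration_map")
  }
  if (!length(scores)) return(numeric(0))
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop_invalid("scores must lie in [0, 1]")
  }
  out <- switch(map$method,
    identity = scores,
    platt = apply_platt(map, scores),
    beta = apply_beta(map, scores),
    spline = apply_spline(map, scores),
    stop_invalid("unknown calibration method: ", map$method)
  )
  pmin(pmax(out, 0), 1)
}

#' @param object,newdata,... `predict` method arguments: a fitted
#'   [calibration_map] and the scores to calibrate.
#' @rdname apply_map
#' @export
predict.calibration_map <- function(object, newdata, ...) {
  apply_map(object, newdata)
}

#' Check a calibration map for monotonicity
#'
#' Evaluates the map on an equally spaced grid and reports whether the
#' output is non-decreasing.  Platt (`beta > 0`) and beta (`a, b >= 0`)
#' maps are monotone by construction; spline maps are monotone-intended
#' only, so this check is used to decide e.g. whether rank-invariance
#' properties apply.
#'
#' @param map A [calibration_map].
#' @param grid_n Grid resolution (default 1001).
#' @return `TRUE` or `FALSE`.
#' @export
map_monotone <- function(map, grid_n = 1001) {
  g <- seq(0, 1, length.out = grid_n)
  out <- apply_map(map, g)
  all(diff(out) >= -1e-12)
}

check_fit_input <- function(scores, labels, min_n) {
  if (length(scores) != length(labels)) {
    stop_invalid("scores and labels must have equal length")
  }
  if (length(labels) < min_n) {
    stop_invalid("calibration fit needs at least ", min_n, " samples")
  }
  if (!all(labels %in% c(0, 1))) {
    stop_invalid("labels must be 0/1")
  }
  if (length(unique(labels)) < 2) {
    stop_invalid("degenerate labels: both classes must be present")
  }
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop_invalid("scores must lie in [0, 1]")
  }
  invisible(TRUE)
}

map_params <- function(params, method) {
  if (inherits(params, "calibration_map")) {
    if (params$method != method) {
      stop_invalid("calibration_map has method ", params$method,
                   ", expected ", method)
    }
    return(params$params)
  }
  params
}

# ---- Serialization --------------------------------------------------------

#' Serialize a calibration map to a structured text file
#'
#' Writes a JSON document with the method tag, the fitted parameters and
#' a format version.  Doubles are written with 17 significant digits so
#' that [read_calibration_map()] reproduces the parameters bit-faithfully.
#'
#' @param map A [calibration_map].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_map <- function(map, path) {
  if (!inherits(map, "calibration_map")) {
    stop_invalid("map must be a calibration_map")
  }
  num <- function(x) {
    if (length(x) == 1) format_full(x) else {
      paste0("[", paste(format_full(x), collapse = ", "), "]")
    }
  }
  lines <- c(
    "{",
    '  "format": "imbcalib-calibration-map",',
    '  "version": 1,',
    sprintf('  "method": "%s",', map$method),
    sprintf('  "fit_n": %s,', ifelse(is.na(map$fit_n), "null", map$fit_n))
  )
  par_lines <- switch(map$method,
    identity = character(0),
    platt = c(
      sprintf('    "alpha": %s,', num(map$params$alpha)),
      sprintf('    "beta": %s', num(map$params$beta))
    ),
    beta = c(
      sprintf('    "a": %s,', num(map$params$a)),
      sprintf('    "b": %s,', num(map$params$b)),
      sprintf('    "c": %s', num(map$params$c))
    ),
    spline = c(
      sprintf('    "knots": %s,', num(map$params$knots)),
      sprintf('    "coefficients": %s,', num(map$params$coefficients)),
      sprintf('    "lambda": %s,', num(map$params$lambda)),
      sprintf('    "lambda_grid": %s,', num(map$params$selection_trace$lambda)),
      sprintf('    "cv_loglik": %s,', num(map$params$selection_trace$cv_loglik)),
      sprintf('    "nfolds": %d,', map$params$nfolds),
      sprintf('    "seed": %d', map$params$seed)
    )
  )
  lines <- c(lines, '  "params": {', par_lines, "  }", "}")
  writeLines(lines, path)
  invisible(path)
}

#' Read a calibration map written by [write_calibration_map()]
#'
#' @param path Path to the serialized map.
#' @return A [calibration_map].
#' @export
read_calibration_map <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (!identical(doc$format, "imbcalib-calibration-map")) {
    stop_invalid(path, " is not a serialized calibration map")
  }
  fit_n <- if (is.null(doc$fit_n)) NA_integer_ else as.integer(doc$fit_n)
  params <- switch(doc$method,
    identity = list(),
    platt = list(alpha = as.numeric(doc$params$alpha),
                 beta = as.numeric(doc$params$beta)),
    beta = list(a = as.numeric(doc$params$a), b = as.numeric(doc$params$b),
                c = as.numeric(doc$params$c)),
    spline = list(
      knots = as.numeric(doc$params$knots),
      knots_score = stats::plogis(as.numeric(doc$params$knots)),
      coefficients = as.numeric(doc$params$coefficients),
      lambda = as.numeric(doc$params$lambda),
      selection_trace = data.frame(
        lambda = as.numeric(doc$params$lambda_grid),
        cv_loglik = as.numeric(doc$params$cv_loglik)
      ),
      nfolds = as.integer(doc$params$nfolds),
      seed = as.integer(doc$params$seed)
    ),
    stop_invalid("unknown calibration method in file: ", doc$method)
  )
  calibration_map(doc$method, params, fit_n = fit_n)
}
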