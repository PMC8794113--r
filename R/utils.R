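# Internal numerical helpers shared across modules.

# Symmetric probability clipping applied before any logit/log transform.
# Keeps every calibration family and distortion finite.
.EPS <- 1e-6

clip_prob <- function(p, eps = .EPS) {
  pmin(pmax(p, eps), 1 - eps)
}

# Evaluate an expression under a given RNG seed without clobbering the
# caller's random number stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-cell seed derivation: cell k of a run with master seed
# `master` uses derive_seed(master, k).  The multipliers are arbitrary
# primes; the modulus keeps the result a valid 32-bit R integer.
derive_seed <- function(master, k) {
  master <- as.double(master) %% 1000003
  as.integer((master * 2053 + as.double(k) * 7919) %% 2147483647)
}

# Bernoulli log-likelihood with possibly fractional targets t.
bernoulli_loglik <- function(eta, t, w = NULL) {
  ll <- t * eta - log1p(exp(pmin(eta, 30))) - pmax(eta - 30, 0)
  if (!is.null(w)) ll <- w * ll
  sum(ll)
}

# Damped Newton fit of a (weighted) logistic likelihood with fractional
# targets; shared by the Platt and beta calibrators and the spline PIRLS.
# X: n x p design; t: targets in [0,1]; w: optional case weights.
# Returns list(coef, converged, iterations).
newton_logistic <- function(X, t, w = NULL, penalty = NULL, lambda = 0,
                            start = NULL, tol = 1e-8, maxit = 100L) {
  p <- ncol(X)
  b <- if (is.null(start)) rep(0, p) else start
  wt <- if (is.null(w)) rep(1, nrow(X)) else w
  pen <- function(b) if (is.null(penalty)) 0 else lambda * drop(crossprod(b, penalty %*% b))
  eta <- drop(X %*% b)
  ll <- bernoulli_loglik(eta, t, wt) - pen(b)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(eta)
    g <- drop(crossprod(X, wt * (t - mu)))
    if (!is.null(penalty)) g <- g - 2 * lambda * drop(penalty %*% b)
    vv <- pmax(mu * (1 - mu), 1e-10) * wt
    H <- crossprod(X * sqrt(vv))
    if (!is.null(penalty)) H <- H + 2 * lambda * penalty
    diag(H) <- diag(H) + 1e-9
    R <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(R)) {
      return(list(coef = b, converged = FALSE, iterations = it))
    }
    step <- backsolve(R, forwardsolve(t(R), g))
    s <- 1
    repeat {
      bn <- b + s * step
      etan <- drop(X %*% bn)
      lln <- bernoulli_loglik(etan, t, wt) - pen(bn)
      if (is.finite(lln) && lln >= ll - 1e-12) break
      s <- s / 2
      if (s < 1e-8) break
    }
    done <- abs(lln - ll) < tol * (abs(ll) + 1) && max(abs(bn - b)) < sqrt(tol)
    b <- bn
    eta <- etan
    ll <- lln
    if (done) {
      converged <- TRUE
      break
    }
  }
  list(coef = b, converged = converged, iterations = it)
}

# Platt's smoothed targets: positives get (N+ + 1)/(N+ + 2), negatives
# 1/(N- + 2).  Prevents infinite parameters under perfect separation.
platt_targets <- function(labels) {
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  ifelse(labels == 1, (np + 1) / (np + 2), 1 / (nn + 2))
}

# Full-precision number formatting ("%.17g") so that delimited report and
# serialization files round-trip doubles bit-faithfully.
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}
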