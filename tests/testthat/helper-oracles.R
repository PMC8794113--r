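# Independent brute-force oracles used to check the package's metric and
# interval implementations.  These deliberately share no code with R/:
# everything is computed by naive loops or direct formula transcription.

oracle_confusion <- function(labels, scores, threshold) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(labels)) {
    pred <- scores[i] >= threshold
    if (pred && labels[i] == 1) tp <- tp + 1L
    if (pred && labels[i] == 0) fp <- fp + 1L
    if (!pred && labels[i] == 0) tn <- tn + 1L
    if (!pred && labels[i] == 1) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

oracle_metrics <- function(labels, scores, threshold) {
  cm <- oracle_confusion(labels, scores, threshold)
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  acc <- (cm$tp + cm$tn) / n
  rec <- if (cm$tp + cm$fn == 0) NA_real_ else cm$tp / (cm$tp + cm$fn)
  prec <- if (cm$tp + cm$fp == 0) NA_real_ else cm$tp / (cm$tp + cm$fp)
  f <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else {
    2 * prec * rec / (prec + rec)
  }
  den <- (cm$tp + cm$fp) * (cm$tp + cm$fn) * (cm$tn + cm$fp) * (cm$tn + cm$fn)
  mcc <- if (den == 0) NA_real_ else {
    (cm$tp * cm$tn - cm$fp * cm$fn) / sqrt(den)
  }
  list(accuracy = acc, precision = prec, recall = rec, f_score = f,
       mcc = mcc, counts = cm)
}

# Stepwise average precision by explicit enumeration of PR points at every
# distinct score, descending.
oracle_auprc <- function(labels, scores) {
  npos <- sum(labels == 1)
  cuts <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  prev_rec <- 0
  for (t in cuts) {
    tp <- sum(labels == 1 & scores >= t)
    pp <- sum(scores >= t)
    prec <- tp / pp
    rec <- tp / npos
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

# Binned calibration-gap enumeration: bins ((z-1)/Z, z/Z], score 0 in bin 1.
oracle_ece <- function(labels, scores, Z) {
  m <- length(scores)
  total <- 0
  for (z in seq_len(Z)) {
    lo <- (z - 1) / Z
    hi <- z / Z
    sel <- if (z == 1) scores <= hi else scores > lo & scores <= hi
    if (!any(sel)) next
    total <- total + sum(sel) / m * abs(mean(labels[sel]) - mean(scores[sel]))
  }
  total
}

# Wilson bounds as the roots of the quadratic (p - phat)^2 = z^2 p(1-p)/n,
# algebraically distinct from the closed form used in R/wilson.R.
oracle_wilson <- function(phat, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  a <- 1 + z^2 / n
  b <- -(2 * phat + z^2 / n)
  cc <- phat^2
  disc <- sqrt(b^2 - 4 * a * cc)
  c(lower = (-b - disc) / (2 * a), upper = (-b + disc) / (2 * a))
}

# Exhaustive grid search for the F-optimal threshold (step 1e-3).  The
# grid is built as (0:k)/k so each point is the double nearest the
# decimal lattice value (seq() accumulates representation error and can
# miss scores that sit exactly on the lattice).
oracle_grid_threshold <- function(labels, scores, step = 1e-3) {
  grid <- (0:round(1 / step)) / round(1 / step)
  best_f <- -Inf
  best_t <- NA_real_
  for (t in grid) {
    m <- oracle_metrics(labels, scores, t)
    if (!is.na(m$f_score) && m$f_score > best_f) {
      best_f <- m$f_score
      best_t <- t
    }
  }
  list(threshold = best_t, f = best_f)
}

# Direct transcription of the calibration-map formulas (power/exp form,
# not plogis), for checking apply_platt / apply_beta elementwise.
oracle_platt_eval <- function(alpha, beta, z) {
  u <- log(z / (1 - z))
  1 / (1 + exp(-(alpha + beta * u)))
}

oracle_beta_eval <- function(a, b, c, z) {
  1 / (1 + (1 / exp(c)) * (1 - z)^b / z^a)
}

# Small random binary instance with both classes present.
random_instance <- function(n, seed, round_scores = NA) {
  set.seed(seed)
  labels <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
  labels <- sample(labels)
  scores <- runif(n)
  if (!is.na(round_scores)) scores <- round(scores, round_scores)
  list(labels = labels, scores = scores)
}

# Label vector with both classes, approximately the requested prevalence.
gen_labels_for_test <- function(n, prevalence, seed) {
  set.seed(seed)
  lab <- rbinom(n, 1, prevalence)
  if (sum(lab) == 0) lab[1] <- 1L
  if (sum(lab) == n) lab[1] <- 0L
  as.integer(lab)
}

# Platt's smoothed targets, re-derived independently for tests.
platt_targets_for_test <- function(labels) {
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  ifelse(labels == 1, (np + 1) / (np + 2), 1 / (nn + 2))
}
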