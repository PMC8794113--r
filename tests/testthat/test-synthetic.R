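test_that("make_imbalanced_labels produces exact class counts", {
  cases <- list(
    list(n_neg = 1000L, ratio = 0.2, pos = 200L),
    list(n_neg = 226L, ratio = 0.2, pos = 45L),
    list(n_neg = 500L, ratio = 1.0, pos = 500L),
    list(n_neg = 226L, ratio = 0.6, pos = 136L),
    # round-half-to-even: 0.8 * 226 = 180.8 -> 181 under our stated rule
    list(n_neg = 226L, ratio = 0.8, pos = 181L)
  )
  for (cs in cases) {
    lab <- make_imbalanced_labels(dataset_spec(cs$n_neg, cs$ratio, seed = 3))
    expect_identical(sum(lab == 1), cs$pos)
    expect_identical(sum(lab == 0), cs$n_neg)
  }
})

test_that("label generation is deterministic and shuffled", {
  spec <- dataset_spec(100, 0.5, seed = 42)
  a <- make_imbalanced_labels(spec)
  b <- make_imbalanced_labels(spec)
  expect_identical(a, b)
  spec2 <- dataset_spec(100, 0.5, seed = 43)
  expect_false(identical(a, make_imbalanced_labels(spec2)))
  # not sorted: positives interleaved
  expect_gt(length(rle(a)$lengths), 3)
})

test_that("invalid dataset specs are rejected", {
  expect_error(dataset_spec(0, 0.5), "n_negative")
  expect_error(dataset_spec(100, 0), "ratio")
  expect_error(dataset_spec(100, 1.2), "ratio")
  expect_error(dataset_spec(2, 0.1), "no positive")
})

test_that("latent posteriors collapse to the prevalence at d = 0", {
  lab <- make_imbalanced_labels(dataset_spec(100, 0.25, seed = 1))
  p <- generate_latent_scores(lab, separability = 0, seed = 5)
  expect_equal(p, rep(mean(lab == 1), length(lab)), tolerance = 1e-12)
})

test_that("latent posteriors are calibrated by construction", {
  # ECE(true posteriors, labels) < 0.02 at n = 1e5 in >= 95% of seeds
  ok <- 0
  for (s in 1:20) {
    lab <- gen_labels_for_test(1e5, 0.5, s)
    p <- generate_latent_scores(lab, separability = 2, seed = 1000 + s)
    ok <- ok + (ece(lab, p, n_bins = 10) < 0.02)
  }
  expect_gte(ok, 19)
})

test_that("high separability drives AUPRC of the posteriors to 1", {
  lab <- gen_labels_for_test(2000, 0.5, 7)
  p <- generate_latent_scores(lab, separability = 12, seed = 8)
  expect_gt(auprc(lab, p), 0.999)
})

test_that("prevalence argument must match the labels", {
  lab <- c(0L, 0L, 1L, 1L)
  expect_error(generate_latent_scores(lab, 1, prevalence = 0.3), "prevalence")
})

test_that("distortions are strictly monotone and stay in (0, 1)", {
  lab <- gen_labels_for_test(3000, 0.5, 11)
  p <- generate_latent_scores(lab, 2, seed = 12)
  # families whose output stays inside the clamp interval at this
  # separability: rank order is preserved exactly (Spearman = 1)
  mild <- list(
    distortion_spec("identity"),
    distortion_spec("platt_family", list(alpha = -2, beta = 4)),
    distortion_spec("beta_family", list(a = 2, b = 1, c = 0.5))
  )
  for (d in mild) {
    z <- distort_scores(p, d, labels = lab)
    expect_true(all(z >= 0 & z <= 1))
    expect_identical(rank(as.numeric(z)), rank(p))
    expect_equal(cor(p, as.numeric(z), method = "spearman"), 1)
  }
})

test_that("steep distortions tie only at the clamp boundary", {
  # a strongly overconfident map or a large downward shift pushes tail
  # scores onto the [eps, 1 - eps] clamp, where ties are deliberate
  # (identical to the clipping every calibrator applies); the map must
  # remain non-decreasing everywhere and strictly increasing inside
  lab <- gen_labels_for_test(3000, 0.5, 11)
  p <- generate_latent_scores(lab, 2, seed = 12)
  eps <- 1e-6
  steep <- list(
    distortion_spec("platt_family", list(alpha = 0, beta = 0.5)),
    distortion_spec("majority_collapse")
  )
  for (d in steep) {
    z <- as.numeric(distort_scores(p, d, labels = lab))
    expect_true(all(z >= eps & z <= 1 - eps))
    zs <- z[order(p)]
    dz <- diff(zs)
    expect_true(all(dz >= 0))
    interior <- zs > eps & zs < 1 - eps
    strict <- interior[-length(zs)] & interior[-1]
    expect_true(all(dz[strict] > 0))
    # ties, if any, sit exactly on the clamp values
    tied <- zs[c(dz == 0, FALSE)]
    expect_true(all(tied %in% c(eps, 1 - eps)))
  }
})

test_that("identity and neutral beta distortions are passthroughs", {
  expect_equal(distort_scores(c(0.3, 0.7), distortion_spec("identity")),
               c(0.3, 0.7))
  d <- distortion_spec("beta_family", list(a = 1, b = 1, c = 0))
  expect_equal(distort_scores(c(0.1, 0.4, 0.9), d), c(0.1, 0.4, 0.9),
               tolerance = 1e-9)
})

test_that("beta_family distortion inverts the beta calibration map", {
  p <- seq(0.02, 0.98, by = 0.02)
  d <- distortion_spec("beta_family", list(a = 2, b = 1, c = 0.5))
  z <- distort_scores(p, d)
  back <- apply_beta(list(a = 2, b = 1, c = 0.5), z)
  expect_equal(back, p, tolerance = 1e-6)
})

test_that("majority_collapse pushes every positive score below 0.5", {
  for (s in 1:5) {
    ss <- make_score_set(300, 0.2, distortion_spec("majority_collapse"),
                         seed = s)
    expect_lt(max(ss$score[ss$label == 1]), 0.5)
    cm <- confusion(ss$label, ss$score, 0.5)
    expect_identical(cm$tp, 0L)
  }
})

test_that("an insufficient explicit collapse shift is an error", {
  lab <- gen_labels_for_test(500, 0.5, 3)
  p <- generate_latent_scores(lab, 2, seed = 4)
  d <- distortion_spec("majority_collapse", list(delta = 1e-3))
  expect_error(distort_scores(p, d, labels = lab), "below 0.5")
})

test_that("invalid distortion parameters are rejected", {
  expect_error(distortion_spec("beta_family", list(a = -1)), "a > 0")
  expect_error(distortion_spec("platt_family", list(beta = 0)), "beta > 0")
  expect_error(distortion_spec("identity", list(a = 1)), "no parameters")
  expect_error(distortion_spec("majority_collapse", list(delta = -2)),
               "delta > 0")
})

test_that("build_study_sets keeps the test partition fixed and balanced", {
  tmpl <- dataset_spec(226, seed = 5, test_negative = 100,
                       test_positive = 100)
  sets <- build_study_sets(tmpl, c(0.2, 0.6, 1.0),
                           distortion_spec("identity"))
  expect_named(sets, c("0.2", "0.6", "1.0"))
  for (r in names(sets)) {
    expect_identical(table(sets[[r]]$test$label),
                     table(c(rep(0L, 100), rep(1L, 100))))
  }
  expect_identical(sum(sets[["0.2"]]$cal$label == 1), 45L)
  expect_identical(sum(sets[["0.6"]]$cal$label == 1), 136L)
  expect_identical(sum(sets[["1.0"]]$cal$label == 1), 226L)
})

test_that("study-set generation is bit-reproducible from the master seed", {
  tmpl <- dataset_spec(150, seed = 99)
  d <- distortion_spec("platt_family")
  a <- build_study_sets(tmpl, c(0.4, 1), d)
  b <- build_study_sets(tmpl, c(0.4, 1), d)
  expect_identical(a, b)
})

test_that("score sets validate their invariants", {
  expect_error(score_set(1:3, c(0, 1), c(0.5, 0.5)), "equal length")
  expect_error(score_set(1:2, c(0, 2), c(0.5, 0.5)), "labels")
  expect_error(score_set(1:2, c(0, 1), c(0.5, 1.5)), "scores")
  expect_error(score_set(1:2, c(0, 1), c(0.5, 0.5), true_probs = c(2, 0)),
               "true_probs")
})

test_that("score files round-trip exactly and reject malformed input", {
  ss <- make_score_set(50, 0.5, distortion_spec("beta_family"), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scores(ss, path)
  back <- read_scores(path)
  expect_identical(back$label, ss$label)
  expect_identical(back$score, ss$score)
  expect_identical(back$true_prob, ss$true_prob)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,label,score", "a,1,0.5", "b,0,1.2"), bad)
  expect_error(read_scores(bad), "line 3")
  writeLines(c("id,label,score", "a,2,0.5"), bad)
  expect_error(read_scores(bad), "line 2")
  writeLines(c("id,score", "a,0.5"), bad)
  expect_error(read_scores(bad), "label")
})
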