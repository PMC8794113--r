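# imbcalib

Probability calibration and threshold selection for class-imbalanced
binary classifiers.

## The problem

Medical image classifiers are usually trained on data where normal
samples far outnumber abnormal ones. The resulting models tend to emit
positive-class probabilities biased toward the majority class: a model
can rank patients perfectly and still place *every* disease-positive
sample below the conventional decision threshold of 0.5, making
F-score and the Matthews correlation coefficient (MCC) undefined
(TP = 0). Post-hoc **calibration** rescales the scores so that among
samples scored near *p*, a fraction *p* is truly positive
(`P(Y = 1 | score = p) = p`); whether that rescaling actually improves
*classification* performance depends on the decision threshold.

`imbcalib` is a reusable, tested pipeline for studying exactly this
question. It provides:

* a **synthetic score generator** with a known ground-truth calibration
  map: imbalance-controlled labels (positives =
  `round(ratio x negatives)`), exact Bayes posteriors
  `p = plogis(d*x + qlogis(prevalence))` from a Gaussian latent model
  (calibrated by construction), and strictly monotone miscalibration
  distortions (logistic-linear over/underconfidence, beta-family
  skew, majority-class collapse);
* three **calibration maps**, all fit on the log-odds of the score:
  Platt scaling `p = plogis(alpha + beta*qlogis(z))`, beta calibration
  `p = (1 + exp(-c)(1-z)^b / z^a)^-1`, and a natural cubic
  smoothing-spline calibrator with penalized Bernoulli likelihood and
  cross-validated smoothness;
* **evaluation**: confusion metrics with `NA` sentinels for undefined
  cells, stepwise (uninterpolated) AUPRC, reliability tables and
  expected calibration error
  `ECE = sum_z |C_z|/m * |freq(C_z) - mean_pred(C_z)|`,
  and PR-guided optimal thresholds (max F over observed-score
  candidates, `>=` decision rule);
* **inference**: Wilson 95% score intervals for ECE/accuracy/F and for
  MCC via the affine `(mcc+1)/2` transform, with significance as
  interval non-overlap;
* an **experiment driver** sweeping imbalance ratio x calibration
  method x threshold policy into machine-readable tables, plus a small
  CLI (`generate` / `calibrate` / `evaluate` / `experiment`).

## Worked example

Reproduce the headline phenomenon — calibration rescues the default
threshold but cannot beat a rank-preserving baseline at the PR-guided
threshold — on synthetic majority-collapsed scores:

```r
library(imbcalib)

cfg <- experiment_config(
  ratios     = c(0.2, 0.6, 1.0),
  methods    = c("platt", "beta", "spline"),
  template   = dataset_spec(226, test_negative = 100, test_positive = 100),
  distortion = distortion_spec("majority_collapse"),
  seed       = 42
)
res <- run_experiment(cfg)

res$ece_table[res$ece_table$ratio == 0.2, ]
#>   ratio   method       ece     lower     upper   n significant_vs_baseline
#> 1   0.2 baseline 0.4773589 0.4092155 0.5463557 200                      NA
#> 2   0.2    platt 0.2182652 0.1666212 0.2805279 200                    TRUE
#> 3   0.2     beta 0.2225258 0.1704161 0.2850937 200                    TRUE
#> 4   0.2   spline 0.2143870 0.1631744 0.2763645 200                    TRUE

compare_thresholds(res)[, c("ratio", "mcc_cal_default", "mcc_uncal_default",
                            "significant_default", "mcc_cal_optimal",
                            "mcc_uncal_optimal", "significant_optimal")]
#>   ratio mcc_cal_default mcc_uncal_default significant_default mcc_cal_optimal
#> 1   0.2       0.4669351                NA                TRUE       0.6621222
#> 2   0.6       0.4445276                NA                TRUE       0.7103197
#> 3   1.0       0.5955947                NA                TRUE       0.6665647
#>   mcc_uncal_optimal significant_optimal
#> 1         0.6621222               FALSE
#> 2         0.7103197               FALSE
#> 3         0.6665647               FALSE
```

Reading the output: every calibration method cuts the test-set ECE
roughly in half, significantly (non-overlapping 95% Wilson intervals
vs the uncalibrated baseline). At threshold 0.5 the uncalibrated MCC
is `NA` — the collapse distortion pushes all positive scores below
0.5, so TP = 0 — while the best calibrated model reaches MCC ≈ 0.47,
significantly above the degenerate baseline (compared as MCC = 0).
At the PR-guided optimal threshold the calibrated and uncalibrated MCC
are *identical*: the distortion is strictly monotone, ranks are
unchanged, and threshold tuning recovers everything calibration would
have given. `write_report(res, "report/")` emits all tables, per-cell
reliability diagrams and PR curves as CSV plus a `manifest.json`;
reports are byte-identical across reruns with the same seed.

The same machinery runs on real classifier scores: CSV files with
header `id,label,score` pass through `read_scores()` or the
`score_files` field of `experiment_config()`.

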