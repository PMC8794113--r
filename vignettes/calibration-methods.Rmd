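---
title: "Calibration under class imbalance: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration under class imbalance: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imbcalib)
```

## The problem

A binary diagnostic classifier emits a positive-class probability
$z \in [0,1]$ for each sample. The classifier is *calibrated* when
$P(Y = 1 \mid z) = z$: among all samples scored near 0.8, about 80%
are truly positive. Models trained on class-imbalanced data — the
normal case in medical imaging, where negatives far outnumber
positives — are routinely miscalibrated, typically biased toward the
majority class. Miscalibration interacts with the decision threshold:
a model whose scores are all shifted downward can classify *every*
positive sample as negative at the conventional threshold of 0.5 while
still ranking samples perfectly.

`imbcalib` implements the full study design around this phenomenon:
synthetic score generation at controlled imbalance with a known
ground-truth calibration map, three calibration methods, reliability
and error quantification, two threshold policies, and interval-based
significance calls, orchestrated into a deterministic experiment
pipeline.

## The synthetic world

The generator replaces GPU-trained image classifiers with an analytic
model chosen so that *perfectly calibrated scores exist in closed
form*:

* Labels: $n^-$ negatives and $\mathrm{round}(r \cdot n^-)$ positives
  for imbalance ratio $r \in (0,1]$, shuffled under a seed. Rounding is
  round-half-to-even (R's `round`); for a 226-negative design this
  gives 45, 90, 136, **181**, 226 positives at
  $r = 0.2, \dots, 1.0$ — the 181 reflects our single documented rule
  where published set constructions are internally inconsistent at
  $0.8 \times 226 = 180.8$.
* Latent features: $x \mid y \sim N(\pm d/2,\, 1)$, with separability
  $d \ge 0$. The exact Bayes posterior of this model is
  $p = \operatorname{logistic}(d x + \operatorname{logit} \pi)$ with
  $\pi$ the prevalence; these posteriors are calibrated *by
  construction*, which the tests verify empirically (ECE $< 0.02$ at
  $n = 10^5$). The default $d = 2$ yields balanced accuracy
  $\Phi(1) \approx 0.84$ — a moderately strong classifier typical of
  the application area.
* Miscalibration: a strictly increasing distortion applied to the
  posteriors. All families act on the log-odds
  $u = \operatorname{logit}(p)$:

  | family | map (posterior $\to$ score) | emulates |
  |---|---|---|
  | `identity` | $z = p$ | a calibrated model |
  | `platt_family` | $z = \operatorname{logistic}((u - \alpha)/\beta)$ | logistic-linear miscalibration; $\beta < 1$ overconfident, $\beta > 1$ underconfident |
  | `beta_family` | inverse of $p = \operatorname{logistic}(c + a \ln z - b \ln(1-z))$ | skewed score distributions |
  | `majority_collapse` | $z = \operatorname{logistic}(u - \delta)$ | bias toward the majority class |

  With `delta = NULL`, `majority_collapse` chooses the shift from the
  generated sample so that the most confident positive lands at score
  0.45 — the degenerate regime in which every disease-positive sample
  falls below the 0.5 threshold (TP = 0, F and MCC undefined) holds by
  construction in every generated split.

Probabilities are clipped to $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-6}$ before any log-odds transform, and distortion
outputs are clamped to the same interval: mathematically every family
maps into $(0,1)$, but a steep distortion can saturate to exactly 0 or
1 in double precision, which would give infinite log-odds downstream.
A consequence worth stating plainly: a very steep distortion ties its
most extreme tail samples *at* the clamp boundary, so exact rank
preservation holds on the clamp interior, with boundary ties shared
consistently by the generator and every calibrator (they clip at the
same $\varepsilon$) — which is precisely what keeps the AUPRC
rank-invariance exact end to end.

**What the generator does not emulate.** There is no training step:
scores do not depend on what the calibration split looks like, so
effects that arise from *model fitting* under imbalance (feature
learning, majority-class gradient dominance) are out of scope. A green
test establishes that the calibration and evaluation machinery behaves
correctly on miscalibrated scores of known structure — not that any
particular neural network is miscalibrated in this way. One
training-driven phenomenon survives in reduced form: when the test
split inherits the imbalance ratio, the prior term
$\operatorname{logit} \pi$ rises with the ratio and recall at 0.5
rises with it.

## The calibrators

All three calibrators are fit on a calibration split and applied to a
held-out test split; they all act on the log-odds
$u = \operatorname{logit}(\operatorname{clip}(z))$ of the raw score.
This is a deliberate interpretation: Platt's method is defined for an
unbounded classifier output, and for a probability-valued score the
canonical unbounded representation is its log-odds. Operating on raw
$z$ instead is not jointly satisfiable with keeping scores in $[0,1]$,
preserving rank order exactly, and recovering the generating
parameters — we verified numerically that the raw-score reading forces
clipping of roughly half of all inverse-distorted scores at realistic
separability, which biases the recovered slope by over 30%.

* **Platt scaling** fits
  $p = \operatorname{logistic}(\alpha + \beta u)$ by damped Newton
  (tolerance $10^{-8}$, at most 100 iterations) on Platt's smoothed
  targets $t^+ = (N^+ + 1)/(N^+ + 2)$, $t^- = 1/(N^- + 2)$, which keep
  the parameters finite under perfect separation. $(\alpha, \beta) =
  (0, 1)$ is the identity. A fitted $\beta \le 0$ (negatively oriented
  scores) warns rather than fails. Constant scores fix $\beta = 0$ and
  return the smoothed prevalence.
* **Beta calibration** fits the logistic-likelihood regression of the
  labels on $(\ln z,\ -\ln(1-z))$, giving
  $p = \bigl(1 + e^{-c} (1-z)^b / z^a\bigr)^{-1}$. Monotonicity
  requires $a, b \ge 0$; a negative slope is set to zero and the model
  refitted without that feature (drop-and-refit, the reference
  behavior), falling back to an intercept-only model if both slopes
  drop. $(a,b,c) = (1,1,0)$ is the identity, so beta calibration
  leaves an already calibrated classifier essentially unchanged — the
  tests check the fitted map stays within 0.02 of $y = x$ on large
  calibrated samples.
* **Spline calibration** fits a natural cubic smoothing spline $f(u)$
  maximizing the penalized Bernoulli log-likelihood
  $\sum_i [y_i f(u_i) - \log(1 + e^{f(u_i)})] - \lambda \int f''^2$,
  with the natural-cubic ("cr") basis of **mgcv** on
  $\min(n, 40)$ knots at quantiles of $u$. The nuisance parameter
  $\lambda$ is selected from a log-spaced 20-point grid
  ($10^{-4} \dots 10^2$) by highest held-out log-likelihood under a
  fixed, seed-controlled 5-fold split — the selection criterion of the
  reference method is not published, so this rule is a documented
  stand-in. For speed at large $n$ the grid search aggregates the data
  over at most 1000 quantile bins of $u$ (the covariate-discretization
  trick of `mgcv::bam(discrete = TRUE)`); the final fit at the
  selected $\lambda$ uses the raw data. As $\lambda \to \infty$ the
  fit collapses to the penalty null space — affine in $u$ — which
  contains both the identity and every `platt_family` distortion
  inverse.

Two numerical consequences worth knowing. First, on perfectly
calibrated data the truth ($f(u) = u$) sits at $\lambda = \infty$, so
cross-validation selects the grid cap and the fitted map sits within
about 0.02–0.03 of the identity on a 99-point grid at $n = 50{,}000$ —
occasionally just above 0.03, which is why the corresponding test is a
seed-majority property. Second, spline fits routinely carry interior
wiggles of order $10^{-4}$: monotonicity is *checked and reported*
(`map_monotone()`), never enforced, and rank-based invariants are
asserted only for strictly increasing fits.

Fitted maps serialize to JSON with numbers written as `%.17g`, so a
write/read round trip reproduces every parameter bit-faithfully.

## Evaluation

* **Confusion and thresholded metrics** use the rule
  "score $\ge$ threshold $\Rightarrow$ positive" at *every* threshold,
  including the boundary. Accuracy, precision, recall, F-score and MCC
  are exact ratios; a metric whose defining denominator is zero is
  `NA` — a value, not an error, because the degenerate TP = 0 regime
  is precisely one of the phenomena under study.
* **AUPRC** is stepwise average precision with ties grouped at equal
  scores and no interpolation (interpolated PR areas are biased, and
  the uninterpolated sum is reproducible bit-for-bit). It is a pure
  rank statistic: any strictly increasing calibration map leaves it
  *exactly* unchanged, and the pipeline asserts this equality per
  cell.
* **Reliability and ECE** use $Z$ equal-width bins $((z-1)/Z, z/Z]$
  (default $Z = 10$; the bin count is our choice, as none is published
  for the reference tables), a score of exactly 0 assigned to bin 1,
  and $\mathrm{ECE} = \sum_z \frac{|C_z|}{m} |\mathrm{freq}(C_z) -
  \overline{\mathrm{pred}}(C_z)|$ over non-empty bins. The default
  `positive_fraction` mode bins the positive-class score against the
  per-bin fraction of positives (the axes of a binary reliability
  diagram); the `confidence` mode bins $\max(z, 1-z)$ against argmax
  correctness.
* **PR-guided threshold**: candidates are the distinct observed scores
  plus 0.5; F is computed at each; the argmax wins, ties broken toward
  the smallest threshold. This equals exhaustive grid search and, by
  construction, never yields a lower F than 0.5 on the selection data.
* **Wilson intervals** (95% default) are attached to ECE, accuracy, F
  and MCC. ECE, accuracy and F are treated directly as proportions.
  MCC is mapped to $(\mathrm{MCC}+1)/2$, the interval computed on the
  proportion scale, and mapped back — keeping bounds in $[-1,1]$ and
  preserving the boundary. This affine treatment is an interpretation,
  flagged here prominently: a Wilson interval is a proportion method,
  and applying it to MCC and ECE mirrors how reported study tables
  use it, not a distributional claim. **Significance** is interval
  non-overlap — the only procedure interval tables support — which is
  conservative relative to a direct $p < 0.05$ test.

## The experiment pipeline

`run_experiment()` sweeps imbalance ratios; per ratio it fits every
requested method on the calibration split, ranks methods by test-split
ECE (ties broken platt < beta < spline for determinism), and produces
the table analogues: per-method ECE with intervals and
significance-vs-baseline flags; calibrated-vs-uncalibrated metrics at
0.5; PR-guided thresholds; metrics at those thresholds; reliability
tables and PR curves per cell. Per-cell seeds derive from the master
seed via a documented counter scheme (`derive_seed(master, 10*i + k)`),
so any cell is re-runnable in isolation. Two runs with the same
configuration and seed produce byte-identical report files.

Open design points and how they were resolved:

* *Where calibrators are fit*: on the held-out calibration split,
  never on the evaluation split (the source workflow is ambiguous; a
  leakage-free default is the defensible choice).
* *Where PR thresholds are selected*: on the test split by default
  (`select_on = "test"`, the apparent practice behind reported
  optimal-threshold tables), with `select_on = "cal"` as the
  leakage-free alternative; the manifest records which was used.
* *Degenerate baselines*: when the uncalibrated MCC is undefined
  (TP = 0 at 0.5), the significance comparison substitutes MCC = 0 —
  the natural value for a degenerate confusion matrix — and flags the
  row `baseline_degenerate`. NA metrics never abort a run; they render
  as the literal token `NA` in reports.
* *Fixed test partition*: by default the test split is the same
  balanced design at every ratio, so only the fitting partition's
  positive count varies; `fixed_test = FALSE` lets the test split
  inherit the ratio.

A worked consequence of this design, reproduced in the test suite 100
times over: under `majority_collapse` at ratio 0.2 the uncalibrated
model has F = MCC = `NA` at threshold 0.5 while the best calibrated
model's MCC is significantly above the degenerate baseline; at the
PR-guided threshold the two are *identical* — a monotone distortion
preserves ranks, so both sides select threshold cuts realizing the
same confusion matrix, and the apparent benefit of calibration
vanishes. Calibration makes the default threshold usable; it does not
improve the classifier's ranking.

## Known limitations

* No training dynamics: imbalance affects only label counts and the
  prior term of the posterior, not feature quality.
* The spline's $\lambda$ selection rule and fold count are stand-ins
  for an unpublished criterion; results at the grid boundaries depend
  on the grid.
* Isotonic regression, temperature scaling, ROC-based threshold rules
  (G-means, Youden J), multi-class calibration and calibrator
  ensembles are deliberately out of scope.
* Wilson intervals on MCC and ECE are a pragmatic convention, not an
  exact sampling theory; the non-overlap significance rule is
  conservative.
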