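Package: imbcalib
Title: Probability Calibration and Threshold Selection for
    Class-Imbalanced Binary Classifiers
Version: 0.1.0
Authors@R:
    person("Imbcalib", "Developers", email = "imbcalib@example.org",
           role = c("aut", "cre"))
Description: Tools for studying probability calibration of binary
    diagnostic classifiers under class imbalance.  Fits Platt, beta and
    smoothing-spline calibration maps to classifier scores, quantifies
    miscalibration with reliability tables and the expected calibration
    error (ECE), selects classification thresholds (default 0.5 or
    precision-recall guided), attaches Wilson score confidence intervals
    to reported metrics, and orchestrates imbalance-sweep experiments
    over synthetic miscalibrated scores with a known ground-truth
    calibration map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mgcv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
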