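Package: wristcal
Title: Wrist-Worn Accelerometer Sedentary Cut-Point Calibration for Children
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating wrist-worn accelerometer count thresholds
    that separate seated sedentary behaviour from light-intensity walking in
    young children. Includes a synthetic epoch-count generator (zero-inflated
    lognormal marginals matched to published per-activity quantiles, a
    Gaussian cross-wrist copula, and child-level random effects), readers and
    writers for an ActiLife-style epoch CSV dialect, direct-observation
    inclusion filtering, dominant versus non-dominant quantile contrasts with
    child-clustered bootstrap confidence intervals, k-fold ROC cut-point
    derivation with held-out validation, and application of cut-points to
    estimate minutes spent sedentary.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    quantreg
Config/testthat/edition: 3
RoxygenNote: 7.3.3
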