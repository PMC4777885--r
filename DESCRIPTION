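Package: telealert
Title: Alert Algorithms for Heart-Failure Telemonitoring of Weight and
    Transthoracic Bio-Impedance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluation framework for threshold-alert algorithms that flag
    impending heart-failure decompensation from daily home-telemonitoring of
    body weight and noninvasive transthoracic bio-impedance (NITTI). Provides
    three output-index algorithms (rule-of-thumb day differences, moving
    average convergence divergence, and one-sided standardized CUSUM control
    charts), guideline weight-rule presets, causal gap imputation and
    adherence accounting, two-week window segmentation with true/false alarm
    labeling, ROC and partial-AUC threshold optimization with Youden operating
    points, false alarms per patient-year, mixed-effect comparison of period
    means, stratified leave-patient-out cross-validation, and a synthetic
    cohort generator emulating the data structure of daily telemonitoring
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
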