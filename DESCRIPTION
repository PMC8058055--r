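Package: normdev
Title: Normative Neurodevelopmental Modeling of Regional Brain Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for normative modeling of regional brain features in
    developmental cohorts. Fits per-region Gaussian-process normative models
    of a cortical feature (e.g., regional volume) on healthy training
    subjects and scores individuals as deviation z-scores that combine
    predictive uncertainty with learned normative variance. Includes
    repeated cross-validated ridge prediction of orthogonal psychopathology
    dimensions from deviation or raw features with permutation-based
    significance and a paired exact test of performance differences,
    ROI-level bootstrap comparisons of correlation effect sizes against the
    general psychopathology factor, matched case-control Cohen's d maps
    with spatial-overlap analysis, and a synthetic cohort generator that
    reproduces the statistical structure these analyses assume so the whole
    pipeline is testable without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
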