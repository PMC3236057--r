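Package: bosn2
Title: Single-Breath Nitrogen Washout Analysis for Bronchiolitis
    Obliterans Surveillance After Lung Transplantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the alveolar (phase III) slope of the
    single-breath nitrogen washout test as a diagnostic and predictive
    marker of the bronchiolitis obliterans syndrome (BOS) in double lung
    and heart-lung transplant recipients. Extracts the alveolar slope and
    closing point from raw washout tracings by two-segment piecewise
    linear least squares, tracks per-variable post-transplant baselines
    (mean of the two highest qualifying measurements), stages visits on
    the FEV1 percent-of-baseline BOS scale, calibrates cut-off values to
    a target specificity on stable patients, computes per-measurement
    operating characteristics, and computes the "predictive ability" of
    an abnormal result: among abnormal results obtained before a BOS
    diagnosis, the percentage that precede a later diagnosis. A seeded
    synthetic-cohort generator emulates the longitudinal structure of a
    three-year transplant follow-up programme so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
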