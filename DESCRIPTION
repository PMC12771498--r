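Package: dprfeas
Title: Dynamic Plan Repository Feasibility Analysis for Online Adaptive
    Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to assess how often previously generated treatment plans
    could be reused in online adaptive radiotherapy. Given a multi-fraction
    course of plans, 3-D dose grids and daily/verification anatomies, the
    package evaluates dose-volume metrics for every plan in a Dynamic Plan
    Repository against graded clinical-goal constraint tables, derives an
    empirical current-clinical-practice benchmark from pooled verification
    dose statistics, scores per-fraction plan acceptability under three
    criteria, and aggregates acceptability frequencies across a cohort.
    A seeded synthetic pelvic-phantom cohort generator (rigid interfraction
    motion, intrafraction drift, organ filling variation, progressive
    prostate swelling, conformal analytic dose) makes the whole pipeline
    runnable and testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
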