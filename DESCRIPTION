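Package: hepascore
Title: Preoperative Mortality Risk Scores for Liver Resection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calculators for three preoperative scoring systems used to
    estimate the risk of death within 90 days of hepatectomy: an
    eight-component additive mortality risk score, the laboratory Model for
    End-stage Liver Disease score (labMELD), and the Portsmouth POSSUM
    mortality equation (P-POSSUM).  Includes the statistical machinery used
    to validate such scores against an observed binary outcome (stratified
    mortality tables with odds ratios, Fisher's exact and Mann-Whitney
    tests, Newton-Raphson logistic regression, ROC curves with C-index and
    paired DeLong comparisons), a seeded synthetic cohort generator that
    emulates a tertiary-centre hepatectomy case mix, and a file-based
    pipeline for scoring and validating patient-level CSV cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
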