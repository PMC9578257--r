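Package: carecascade
Title: Cascade-of-Care Quality Assessment for Integrated Type 2 Diabetes Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multilevel data framework for assessing the quality of integrated
    type 2 diabetes care from linked health-insurance claims and laboratory data.
    Provides a seeded generator of Belgian-style claims, pharmaceutical, laboratory
    and practice tables; algorithmic claims-based identification of the type 2
    diabetes cohort (medication and pre-diabetes-pass proxies with type 1 exclusion
    rules); an emulation of pseudonymized two-trusted-third-party record linkage of
    claims-side and lab-side records; the six-stage cascade of care (tested,
    diagnosed, in care, in treatment, followed up, under glycaemic control) with
    stratified bar and leakage reporting; Assessment of Chronic Illness Care (ACIC)
    scoring; and logistic and random-intercept multilevel models relating cascade
    drops to patient and practice characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lme4,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
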