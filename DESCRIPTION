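Package: warfpgx
Title: Pharmacogenetic Warfarin Dose Prediction and Retrospective Model Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retrospective evaluation of CYP2C9/VKORC1-based
    warfarin dosing in an anticoagulation cohort. Implements PCR-RFLP
    genotype calling from restriction-fragment patterns, genotype and
    allele frequency summaries with Hardy-Weinberg equilibrium testing,
    the IWPC pharmacogenetic and clinical dosing equations plus a
    fixed-dose comparator, INR computation from prothrombin time,
    empirical stable-dose determination from visit histories, and the
    full battery of model-performance statistics (mean absolute error,
    regression, 20 percent dose classification, event rates, absolute
    risk reduction, number needed to genotype, bleeding contingency
    analysis). A seeded synthetic-cohort generator reproduces the
    statistical structure of an anticoagulation clinic population so the
    whole pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
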