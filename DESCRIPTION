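Package: gdsirt
Title: IRT-Based Abbreviation of Binary Screening Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for shortening dichotomous screening instruments with item
    response theory, built around the 30-item Geriatric Depression Scale
    (GDS30). Calibrates a two-parameter logistic (2PL) model by marginal
    maximum likelihood, ranks items by discrimination, and performs sequential
    item reduction with a DeLong equivalence stopping rule under split-sample
    cross-validation. Includes ROC/AUC inference (DeLong, Hanley-McNeil),
    Youden cutoff selection, an efficiency-ratio (AUC per item) bootstrap,
    Mantel-Haenszel differential item functioning with ETS classification,
    differential test functioning, and a synthetic-cohort generator that
    emulates a low-prevalence screening population for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
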