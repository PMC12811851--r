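Package: alriscore
Title: Pediatric ALRI Severity Scores and Mortality Discrimination Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for external validation of point-based clinical severity
    scores for pediatric acute lower respiratory tract infection (ALRI).
    Provides a declarative scoring engine bundled with definitions for eight
    published risk scores (RISC HIV-negative, mRISC, RISC-Malawi in MUAC and
    weight-for-age variants, PERCH, PREPARE, ReSVinet, and a
    nutrition-augmented ReSVinet), WHO-threshold anthropometry and vital-sign
    categorization, cohort construction with exclusion-flow accounting,
    discrimination analysis of score totals against in-hospital mortality
    (AUROC with DeLong variance, paired DeLong tests, Youden-J optimal
    cutoffs, age-stratified analysis), Table-1 style descriptive statistics
    with crude (Woolf) and age/sex-adjusted logistic odds ratios, and a
    seeded synthetic admission-cohort generator with a logistic outcome
    model calibrated to a target case fatality rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
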