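Package: pescreen
Title: First-Trimester Preterm Preeclampsia Screening Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for first-trimester combined screening for preterm
    preeclampsia: a fully parameterized competing-risks Bayes engine that
    turns maternal history and biomarker multiples of the median (MAP,
    uterine artery pulsatility index, PAPP-A, PlGF) into a woman-specific
    risk of preeclampsia with delivery before 37 weeks; multiple-of-the-
    median quality control with one-sample t-tests and median re-centering;
    a seeded synthetic cohort generator emulating a screened population
    with configurable population-level MoM miscentering and prophylactic
    aspirin assignment; and screening-performance evaluation (screen-
    positive rate, weighted ROC curves, detection rate at a fixed false-
    positive rate, AUC with bootstrap confidence intervals) including a
    counterfactual adjustment of case counts for aspirin prophylaxis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
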