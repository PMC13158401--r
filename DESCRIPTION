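Package: evscore
Title: Additive Scoring of Serum and Extracellular Vesicle Markers for
    Differentiating HCC from iCCA in LR-M Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for building and stress-testing clinically interpretable
    additive point scores that separate hepatocellular carcinoma (HCC) from
    intrahepatic cholangiocarcinoma (iCCA) among LI-RADS LR-M lesions.
    Implements marker prioritization by L1-penalized logistic regression
    merged with principal-component loading contributions, ROC-Youden
    cut-off derivation and integer additive score assembly (including a
    fixed-cut-off 5-point variant), discrimination statistics (AUROC,
    DeLong comparisons, confusion metrics), robustness certification by
    bootstrap, Monte Carlo measurement-noise perturbation and repeated
    train-test splits, exploratory Kaplan-Meier / log-rank / Cox survival
    stratification, and a calibrated synthetic cohort generator with
    log-normal markers and censored exponential survival for end-to-end
    testing without patient data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    survival,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
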