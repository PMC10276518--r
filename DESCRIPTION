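Package: methcascade
Title: Two-Stage cfDNA Methylation Classifier Cascade for Cancer Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Development and evaluation pipeline for region-level circulating
    cell-free DNA (cfDNA) methylation classifiers. Covers quantification of
    average methylation fractions from bisulfite CpG counts or qPCR Ct values,
    two-stage differentially methylated region (DMR) selection (plasma
    discovery plus tissue/plasma verification), anchor-based forward feature
    selection of ridge-logistic panel classifiers under repeated stratified
    cross-validation, a sequential screening/diagnostic two-model cascade, and
    a diagnostic-accuracy layer with bootstrap confidence intervals and
    prevalence-adjusted predictive values. Includes a beta-binomial synthetic
    cohort generator with a tumor-fraction dilution signal model so the whole
    pipeline is testable end to end without patient data, and a sample-size
    formula for sensitivity/specificity studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
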