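Package: dualsubtype
Title: Dual Molecular Subtype Calling for 80-Gene Breast Cancer Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Correlation-to-centroid molecular subtyping of breast tumors
    against Luminal, Basal and HER2 gene signatures, with single/dual/triple
    subtype calling based on per-sample gene bootstrap and cohort-level
    multimodality detection of score differences. Includes stratified
    resampling of dual-subtype prevalence under a clinical subtype mixture,
    a four-class (BLIA/BLIS/LAR/MES) triple-negative re-classifier, clinical
    subtype derivation rules, the associated cohort statistics (chi-square,
    Welch t, Wilson proportions, logistic regression for pathological
    complete response), and a synthetic cohort generator with planted
    single/dual structure and coupled clinical annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
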