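Package: adipomethyl
Title: Epigenome-Wide Association and Causal Inference for Adiposity Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a multi-ethnic epigenome-wide
    association workflow for general (BMI) and abdominal (waist
    circumference) adiposity: intensity-level methylation array quality
    control and quantile normalization, control-probe principal components
    and reference-based blood cell-type deconvolution, stratified per-CpG
    regression with inverse-variance fixed-effect meta-analysis and
    heterogeneity testing, FDR-based discovery with novelty annotation and
    cross-study direction-consistency tests, two-wave cross-lagged panel
    models for temporal inference, and bidirectional Mendelian
    randomization using cis-mQTL instruments and polygenic risk scores.
    Includes a synthetic two-wave multi-ethnic cohort generator so that
    every stage is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
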