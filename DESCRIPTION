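Package: ProteoSubtype
Title: Proteomic Subtyping and Survival Stratification of Small Cell Lung
    Cancer Cohorts
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for label-free proteomic stratification of small cell
    lung cancer (SCLC) cohorts: iBAQ/FOT quantification with per-sample
    minimum/10 missing-value imputation, two-stage abundance and
    variability feature selection, consensus non-negative matrix
    factorization (KL-divergence multiplicative updates) with
    silhouette- and prognosis-guided selection of the cluster number,
    one-vs-rest signature protein derivation, a random-forest subtype
    classifier with stratified cross-validation, and subtype-stratified
    survival analyses (Kaplan-Meier, log-rank, Cox proportional hazards,
    chemotherapy-benefit and immunotherapy cohort comparisons). Includes
    a synthetic cohort generator that emulates the statistical structure
    of FFPE label-free proteomic cohorts (latent subtypes, planted
    overexpression signatures, abundance-dependent dropout,
    subtype-dependent survival with treatment interactions) so the whole
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    survival,
    randomForest,
    cluster,
    withr,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
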