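Package: pgscontext
Title: Context-Dependent Polygenic Score Performance and Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how personal and environmental covariates
    modify polygenic score (PGS) performance and effect sizes. Provides a
    seed-controlled synthetic biobank-style cohort simulator (polygenic
    trait, SNP-by-age interaction effects, heritable covariates,
    PGS-by-covariate interactions), per-SNP association scans in main,
    SNP-by-age and age-stratified designs, pruning-and-thresholding score
    construction including age-aware (GxAge) scoring, covariate-stratified
    incremental R-squared with bootstrap uncertainty, interaction models
    with a covariate-PGS correction for shared-heritability inflation,
    quantile-regression profiles of PGS effect across phenotype deciles,
    cross-validated LASSO and neural-network model comparison, and an
    orchestrated train/tune/test experiment for scores built directly from
    SNP-by-age GWAS effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
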