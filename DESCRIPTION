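Package: protruler
Title: Proteomic-Ruler Copy Numbers and Proteome Composition Analysis for
    Label-Free Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of label-free protein quantification data:
    histone proteomic-ruler estimation of per-cell protein copy numbers and
    mass, protein-class and subcellular-compartment mass budgets with
    co-localization normalization, protein-complex stoichiometry, cell-type
    marker detection from detection patterns (one-vs-rest Fisher exact
    tests), differential abundance by one-way ANOVA and covariate-adjusted
    ANCOVA with Tukey post hoc comparisons, Fisher-exact term enrichment
    against an explicit background, and validity filtering with down-shifted
    normal imputation of missing values. Includes a synthetic-data generator
    producing atlas-style (cell types and tissues) and cohort-style
    (three-group disease study with age and sex covariates) datasets with
    full ground truth, so every stage of the pipeline can be validated
    against known copy numbers, planted markers and planted effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    emmeans,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
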