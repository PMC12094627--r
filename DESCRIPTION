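Package: famliab
Title: Familial Aggregation and Liability-Threshold Familiality in Family Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Family-based inference for binary disorders in multi-generation
    population cohorts. Builds pedigrees from phenotype tables and enumerates
    relative pairs by class; estimates marginal recurrence-risk ratios
    (lambda_R) by logistic regression with plug-in standardization,
    cluster-robust sandwich variance and delta-method intervals; estimates
    family-clustered tetrachoric correlations for sibling and parent-offspring
    pairs; and estimates liability-threshold familiality and cross-disorder
    familial correlations (Falconer and Reich-corrected estimators with exact
    bivariate-normal oracles) with cluster-bootstrap confidence intervals.
    Includes a synthetic three-generation cohort generator under a
    multivariate liability-threshold model with spousal resemblance and
    selective dropout, and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
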