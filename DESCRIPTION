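Package: gdmprs
Title: Polygenic Risk Scores and Gestational Diabetes Traits in Two-Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying a type-2-diabetes
    polygenic risk score (PRS) against gestational diabetes mellitus (GDM) and
    related glucose traits in two pregnancy cohorts. Provides a synthetic
    two-study cohort generator with genotypes and variant weights; phenotype
    derivation (IADPSG and South-Asian-specific GDM classification from oral
    glucose tolerance tests, trapezoidal glucose area under the curve,
    diet-quality scoring, index-pregnancy selection); PRS scoring with
    p-value-threshold grid search and genotype principal components; linear,
    logistic and interaction models; inverse-variance fixed-effect
    meta-analysis with Cochran's Q and I-squared; model-based population
    attributable fractions with bootstrap intervals; a Gaussian risk-score
    screening converter (odds ratio to detection rate at a fixed
    false-positive rate); and Monte-Carlo power for gene-environment
    interactions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
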