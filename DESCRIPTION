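Package: copath
Title: Genetic Association with Co-Occurring Alzheimer and Lewy Body
    Neuropathology
Version: 1.0.0
Authors@R:
    person("copath", "developers", email = "copath-dev@example.org",
           role = c("aut", "cre"))
Description: Tools for case-control genetic analysis of autopsy cohorts
    scored for both Alzheimer's disease (AD) and Lewy body (LB)
    neuropathology. Provides rule-based classification of individuals into
    AD+/- x LB+/- categories under alternative published-style criteria
    schemes, kinship-based duplicate and relative pruning, per-variant
    quality control (minor allele frequency, Hardy-Weinberg exact test,
    missingness, imputation quality), per-site logistic-regression
    association with demographic and principal-component covariates and a
    Firth fallback for separated data, fixed-effect inverse-variance
    meta-analysis across sites, a known-risk-locus direction-concordance
    enrichment survey, and a synthetic two-site cohort generator with a
    planted allele effect on AD liability for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
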