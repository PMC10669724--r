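Package: gxecross
Title: Gene-Environment Interaction Analysis with Re-Parameterized
    Crossover Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing competing gene-environment interaction
    hypotheses (diathesis-stress, differential susceptibility, vantage
    sensitivity) in cohort studies of child reading achievement.
    Provides genotype coding and SNP quality control (call rate, minor
    allele frequency, Hardy-Weinberg equilibrium), expectation-
    maximization imputation of missing phenotype data, hierarchical
    moderated regression with standardized coefficients and simple
    slopes, Johnson-Neyman regions of significance with proportion-of-
    interaction and proportion-affected indices, sequential Bonferroni
    correction, and a re-parameterized crossover-point regression that
    fits six nested strong/weak interaction models compared by nested
    F-tests and information criteria. A synthetic-cohort generator with
    known ground truth supports validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
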