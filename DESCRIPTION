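Package: ccsens
Title: Cocaine Behavioral Sensitization Analysis for Collaborative Cross Strain Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing cocaine-induced behavioral sensitization measured in
    panels of inbred mouse strains (Collaborative Cross strains and their eight
    founders) under a 19-day open-field protocol. Derives per-mouse sensitization
    phenotypes (habituation, acute response, sensitization area under the curve,
    expression, conditioned activation) from daily locomotor distances; fits
    sex-residualized linear mixed models with a random mouse intercept by profiled
    REML, with Satterthwaite degrees of freedom and Tukey HSD post hocs; estimates
    broad-sense heritability from one-way strain ANOVA mean squares with model-based
    bootstrap standard errors; and computes strain-mean Pearson correlation matrices
    with an autocorrelation mask and Bonferroni flags, including cross-site
    replicability correlations. A synthetic cohort generator with configurable
    variance components supports estimator-recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    lmerTest
Config/testthat/edition: 3
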