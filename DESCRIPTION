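Package: qgdiverge
Title: Evolvability-Divergence Scaling Analyses for Quantitative Genetic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for meta-analyses of the relationship between standing
    genetic variation (mean-scaled evolvability) within populations and
    phenotypic divergence among populations. Provides the evolvability
    algebra of mean-scaled G-matrices (evolvability and conditional
    evolvability along arbitrary directions, eigen summaries), proportional
    divergence statistics from population trait means, weighted random-slope
    mixed-model meta-regression with attenuation correction for estimation
    error in evolvabilities, multivariate eigen-direction analyses with
    Monte-Carlo uncertainty, divergence-vector diagnostics, and a seeded
    synthetic-database generator emulating neutral and optimum-tracking
    divergence for validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    MASS,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
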