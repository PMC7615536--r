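Package: trajmix
Title: Parallel-Process Piecewise Growth Mixture Models for Co-Developing
    Trait Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Joint modelling of two co-developing questionnaire trait series
    (an ADHD symptom scale scored 0-10 and a social-communication scale
    scored 0-24) from childhood to adulthood. Implements a parallel-process
    piecewise linear growth mixture model estimated by full-information
    maximum likelihood with a multi-start ECM algorithm, class enumeration
    statistics (AIC, BIC, relative entropy, an adjusted likelihood-ratio
    test and a parametric bootstrap likelihood-ratio test), bias-corrected
    three-step association of latent trajectory classes with covariates and
    distal outcomes (multinomial three-step, BCH weighting, posterior-
    weighted proportion estimation), and a correlation workflow combining
    Spearman rank correlations, predictive-mean-matching multiple
    imputation with Rubin pooling, and tests comparing dependent
    correlations. A seeded synthetic cohort generator emulating the
    measurement design (bounded integer scales, wave attrition,
    class-linked auxiliary variables) supports simulation studies and
    parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet
Config/testthat/edition: 3
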