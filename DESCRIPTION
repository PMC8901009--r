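Package: vpop
Title: Virtual Patient Populations for In-Silico Cardiovascular Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates virtual patient populations for in-silico
    cardiovascular trials. Fits a joint multivariate log-normal model to a
    real clinical cohort, samples arbitrarily many statistically consistent
    virtual patients, discretizes simulated categorical covariates at
    critical values, imputes missing source values by inverting the sampling
    equation under a least-norm constraint, links virtual clinical records
    to arterial-geometry records by probabilistic record linkage, and
    validates real-versus-virtual agreement with Kolmogorov-Smirnov
    goodness-of-fit, moment, and correlation comparisons. Includes a
    synthetic-cohort generator with known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
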