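Package: vegcalib
Title: Calibration by Double Sampling for Vegetation Change Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconciles coarse categorical historical vegetation surveys with
    quantitative contemporary surveys through calibration by double sampling.
    Provides informative prior constructions (midpoint, uniform, normal,
    truncated normal) for latent historical attribute values, a joint
    hierarchical Bayesian calibration-prediction-change model fitted by MCMC
    (JAGS), a non-calibration Bayesian reinterpretation alternative, deviance
    information criterion model comparison, k-fold cross-validation with
    Fisher-z correlation intervals, management-transition change summaries,
    and a seeded synthetic-data generator for testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: JAGS (>= 4.0.0)
Config/testthat/edition: 3
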