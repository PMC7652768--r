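Package: ehrmix
Title: Bayesian Profile Regression Mixtures for Censored Survival Outcomes
    with Correlated Exposures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits Bayesian profile regression mixture (PRM) models that link a
    right-censored, left-truncated survival outcome to a profile of highly
    correlated exposure covariates through shared cluster membership. The
    disease sub-model is an instantaneous excess hazard ratio model with a
    piecewise-constant baseline hazard on four age intervals; the exposure
    sub-model combines lognormal and multinomial component distributions; the
    attribution sub-model is a truncated stick-breaking Dirichlet process
    mixture. Inference uses an adaptive Metropolis-within-Gibbs sampler with
    three label-switching moves, a restricted variant with a fixed number of
    non-empty clusters, posterior-similarity-matrix post-processing with
    best-partition selection, and DIC/WAIC model comparison. A synthetic
    occupational-cohort simulator emulating a uranium-miner cohort (delayed
    entry, competing mortality, correlated radon, gamma and uranium-dust
    exposures) supports validation without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
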