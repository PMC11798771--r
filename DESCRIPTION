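Package: icarsurv
Title: Bayesian Weibull Accelerated-Failure-Time Models with Household
    Frailty and Besag ICAR Spatial Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits multi-level Weibull accelerated-failure-time (AFT)
    survival models in which the linear predictor combines fixed covariate
    effects, an independent and identically distributed Gaussian household
    frailty, and a Besag intrinsic conditional autoregressive (ICAR)
    spatial effect defined on an areal adjacency graph. Inference is by an
    adaptive Metropolis-within-Gibbs sampler; model variants with either,
    both or neither random effect are compared by DIC and WAIC computed
    from pointwise posterior log-likelihoods. Includes proportional-hazards
    diagnostics (scaled Schoenfeld residual tests), a synthetic-data
    generator for DHS-style clustered survival records with known ground
    truth, time-ratio reporting, and choropleth export of state-level
    spatial effects to GeoJSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
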