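Package: cowear
Title: Cokurtosis-Based Anomaly Detection for Wearable Health Streams
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Real-time anomaly detection in multivariate wearable health
    streams (per-minute heart rate and step counts). Windows of the stream
    are summarized into resting/active/overall heart-rate features, scored
    against a healthy reference distribution via the fourth-order joint
    cumulant (cokurtosis) tensor, its higher-order singular value
    decomposition, a normalized feature-moment metric, and the Hellinger
    distance, and flagged when the score exceeds a threshold. Also provides
    a weight-clipped Wasserstein GAN for per-user digital-twin synthesis,
    a Latin-hypercube perturbation pipeline for growing synthetic
    population cohorts, patient-level F1/false-negative-rate evaluation
    with threshold-uncertainty sweeps, and a synthetic wearable-cohort
    simulator used as the test fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
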