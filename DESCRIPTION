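Package: poolstate
Title: Bayesian Multistate Hidden Markov Models for River-Pool Acoustic
    Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating monthly pool-to-pool movement of
    acoustically tagged river fish with a Bayesian multistate hidden
    Markov model. The package covers the full workflow: simulation of
    receiver deployments, tag cohorts and detection streams from the
    model's own generative structure; screening of suspect tags (dead
    fish and dropped transmitters); reduction of detections to monthly
    pool residencies and receiver-effort covariates; an
    effort-dependent logistic detection model with hierarchical
    pool-level effects; marginal-likelihood computation by the forward
    algorithm; adaptive Markov chain Monte Carlo sampling with
    Gelman-Rubin diagnostics; and posterior movement-matrix and
    detection-curve summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
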