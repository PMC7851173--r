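Package: ctcrwrisk
Title: Covariate-Driven Continuous-Time Correlated Random Walks and
    Vessel-Encounter Risk Mapping for Marine Megafauna
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a continuous-time correlated random walk (CTCRW) to
    Argos satellite telemetry in a single step, letting the velocity
    variability (sigma) and velocity autocorrelation (beta) parameters
    vary along the track as lognormal latent variables driven by
    environmental covariates. Observation error uses the Argos error
    ellipse. Fitting marginalizes the latent parameters and states with
    the Laplace approximation via 'TMB'; an independent pure-R Kalman
    filter, smoother and Laplace marginal are included for validation.
    Downstream layers include persistence and long-term velocity,
    post-hoc behavioural-state quadrants (area-restricted search vs
    transit), spatial long-term-velocity prediction rasters, vessel
    density gridding, relative probabilities of encountering a whale
    (RPEW) and of a vessel encountering a whale (RPVEW), and
    distribution-overlap statistics (Schoener's D, Warren's I). A
    synthetic-data generator produces covariate rasters, tracks and
    vessel records so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    stats,
    utils,
    TMB
LinkingTo:
    TMB,
    RcppEigen
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
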