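Package: dipdcm
Title: Dynamics-Informed Priors for Neural Mass Model Spectral Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a three-population neural mass model to log power spectral
    densities of electrophysiological recordings and infers its parameters by
    a hybrid two-step scheme: a multi-objective genetic algorithm (NSGA-II)
    maps the bounded parameter space to model dynamics, and its best solutions
    seed unit-variance Gaussian priors for repeated variational-Laplace
    inversions whose posteriors are averaged into an equal-weight mixture.
    Includes the linearised transfer-function forward model, stochastic
    time-domain simulation, synthetic-data generation, free-energy and RMSE
    landscape diagnostics, and group-level effect inference with credible
    intervals and standardised effect sizes.
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
    lhs,
    parallel
Suggests:
    deSolve,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
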