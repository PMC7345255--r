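Package: elastid
Title: Multiscale Statistical Identification of Random Elasticity Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification of the deterministic macroscale elasticity tensor
    and of the hyperparameters (mean moduli, dispersion, spatial correlation
    length) of a prior non-Gaussian stochastic model for the mesoscale
    apparent elasticity field of a random heterogeneous linear-elastic
    material, from full-field displacement measurements observed
    simultaneously at macroscale and mesoscale on a single specimen.
    Includes simulation of positive-definite matrix-valued random fields,
    plane-stress and 3D finite-element solvers on structured grids,
    stochastic homogenization with static uniform boundary conditions,
    strain-field dispersion and correlation-length indicators, fixed-point
    and genetic multi-objective optimizers, maximum-likelihood
    robustification across observation windows, and an in-silico generator
    of synthetic multiscale compression experiments.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
Config/testthat/edition: 3
RoxygenNote: 7.3.3
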