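Package: alfgpr
Title: Atomic-Energy Gaussian Process Potentials with Local-Frame Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains and deploys physics-informed Gaussian process regression
    potentials built on per-atom energies that sum to the molecular energy.
    Provides atomic local frame (ALF) feature vectors with exact Cartesian
    Jacobians, a composite squared-exponential/periodic kernel, configurable
    prior mean functions shifted from the training mean up to high-energy
    states, a grey-wolf metaheuristic for kernel hyperparameter search,
    analytic forces via the B-matrix chain rule, NVT/NVE molecular dynamics
    with bond-ratio stability scoring, BFGS geometry optimization,
    diversity-aware farthest-point sub-sampling of conformer pools, and a
    synthetic partitioned potential-energy-surface generator so the full
    train/deploy/score loop runs without quantum-chemistry software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite
Config/testthat/edition: 3
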