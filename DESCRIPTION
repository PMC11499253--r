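Package: lineattractor
Title: Line-Attractor Analysis of Neural Population Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for discovering and characterising slow, approximately
    line-attractor dynamics in calcium-imaging recordings of hypothalamic
    neural populations during social behaviour. Provides a recurrent
    switching linear dynamical system (rSLDS) engine with structured
    variational EM inference, eigenvalue time-constant estimation and a
    line-attractor score, forward-simulation accuracy, flow-field
    visualisation, cross-session latent projection and held-out
    perturbation fitting; single-cell metrics (choice probability,
    autocorrelation half-width, ridge GLMs with neuronal coupling,
    photometry normalisation, frame-wise SVM decoding); an input-driven
    neural integrator model; FORCE-trained rate networks with fixed-point
    analysis; a mechanistic leaky integrate-and-fire network with a
    slow-synapse integration subnetwork; behavioural bout-table analysis;
    and a seeded synthetic-data generator emulating male/female mating
    bout structure and latent attractor dynamics so that every stage is
    testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    e1071,
    jsonlite,
    nnet,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
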