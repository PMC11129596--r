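Package: tedmorph
Title: Total-Evidence Tip Dating from Continuous Morphological Characters
Version: 0.1.0
Authors@R:
    person("tedmorph", "developers", email = "tedmorph@example.org",
           role = c("aut", "cre"))
Description: Bayesian inference of time-calibrated phylogenies from multiple
    correlated continuous characters. Implements the phylogenetic Brownian
    motion likelihood via dense and pruning algorithms (with intraspecific
    variance and shrinkage-estimated character correlations), fossilized
    birth-death and birth-death-sequential-sampling tree models with forward
    simulators, a Metropolis-Hastings MCMC engine over trees and model
    parameters with sampled-ancestor support, synthetic-data generators for
    calibration and accuracy studies, and landmark preprocessing
    (generalized Procrustes superimposition, multidimensional scaling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
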