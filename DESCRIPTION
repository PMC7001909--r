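Package: crcbranch
Title: Two-Type Branching-Process Modelling of Colorectal Adenoma and
    Carcinoma Size Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models colorectal cancer progression as a two-type
    continuous-time branching process with immigration: adenoma cells
    arise from a stem-cell pool, proliferate, die, and seed a malignant
    compartment that itself grows as a birth-death process.  The package
    provides the closed-form negative-binomial size distribution of the
    adenoma compartment, numerical evaluation of the probability
    generating function of the carcinoma compartment, a large-size
    saddle-point approximation to the carcinoma size distribution,
    exact and hybrid (tau-leaping) stochastic simulation, registry-style
    prevalence imputation, composite-likelihood inference by
    Nelder-Mead optimisation and adaptive Markov chain Monte Carlo, and
    individualized estimates of the probability of synchronous cancer
    given an adenoma finding of a given size.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
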