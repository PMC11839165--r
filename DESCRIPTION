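Package: centrosim
Title: Stochastic and Deterministic Models of Centrosome Size Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the maturation of a centrosome pair competing for
    shared cytoplasmic pools of pericentriolar-material subunits and enzyme.
    Implements three growth model families (autocatalytic assembly,
    single-component catalytic assembly in a shared enzyme pool, and a
    two-scaffold-component model with localized or shared enzyme), each with
    an exact Gillespie stochastic simulation and its deterministic mass-action
    twin. Includes the derived analyses: Hill-coefficient cooperativity of
    growth curves, robustness of size equality to initial size differences,
    asymmetry-control efficiency under differential centriole activity,
    centrosome-size scaling with cell size via pool depletion, and
    Stokes-Einstein diffusion estimates. Ships a registry of named parameter
    scenarios reproducing the published figure protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
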