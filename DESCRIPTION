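Package: gfetkin
Title: Enzyme Kinetics Inference for Graphene-FET Peroxidase Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and inference tools for amperometric enzyme assays
    on graphene field-effect transistor (GFET) biosensors. Provides forward
    kinetic models for Michaelis-Menten catalysis and the heme-peroxidase
    catalytic cycle with hydrogen-peroxide-driven suicide inactivation, a
    constant-voltage GFET measurement model with calibration-curve fitting
    and linear-range detection, a synthetic-study generator spanning enzyme,
    pH, temperature and substrate-concentration conditions, Bayesian
    inversion of Michaelis-Menten parameters by adaptive random-walk
    Metropolis MCMC, and a multilayer-perceptron surrogate that predicts
    kinetic parameters across conditions from inversion-derived labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
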