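Package: gsm2
Title: Stochastic Kinetics of Radiation-Induced DNA Damage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Stochastic modelling of radiation-induced DNA lesion kinetics in a
    single cell nucleus. Implements the master equation for the joint law of
    sublethal and lethal lesion counts under repair, direct lethal conversion
    and pairwise lesion interaction; exact Gillespie simulation of sample
    paths and ensembles; exact integration of the truncated master equation
    on the reachable lattice; the macroscopic (microdosimetric kinetic model)
    ODE limit with its closed-form Bernoulli solution; the linear-noise
    (system-size) approximation with first-moment and covariance equations and
    the accumulated correction by which lethal-lesion counts fall below
    Poisson dispersion; and an Euler-Maruyama sampler for the time-dependent
    Ornstein-Uhlenbeck process whose law solves the linear Fokker-Planck
    equation, with an absorbing boundary at zero sublethal lesions. Results
    are returned as tibbles with tidy()/glance() summaries and ggplot2
    autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
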