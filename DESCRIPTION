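Package: fcrnpk
Title: FcRn-Mediated IgG Trafficking Models and Antibody Pharmacokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Mechanistic and noncompartmental analysis of antibody serum
    persistence. Implements a linear three-compartment model of exogenous
    IgG exchange between central, peripheral and endosomal spaces with
    pH-dependent FcRn sorting and surface release, matrix-exponential
    propagation, eigenvalue and Newton-iteration half-life extraction, and
    Bayesian inference of trafficking parameters from beta-phase half-life
    data under affinity-ordered priors with Geweke and autocorrelation
    diagnostics and sensitivity analysis. Supporting tools cover
    noncompartmental pharmacokinetics (log-linear trapezoidal AUC,
    clearance, steady-state volume of distribution), biexponential fitting
    by curve stripping, surface plasmon resonance equilibrium and kinetic
    1:1 binding fits, plasmon-wavelength peak extraction, and seeded
    synthetic-data generators for serum concentration curves, isotherms
    and absorbance spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
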