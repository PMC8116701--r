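Package: iohexolPK
Title: Population Pharmacokinetics of Iohexol for GFR Estimation and
    Optimal Sampling Times in Dogs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating glomerular filtration rate (GFR) from
    sparse iohexol plasma concentrations using a two-compartment
    population pharmacokinetic model with chronic kidney disease status
    and serum creatinine as clearance covariates.  Provides closed-form
    bi-exponential concentration prediction, Monte-Carlo simulation of
    covariate-conditioned profiles, empirical Bayes (MAP) estimation of
    individual clearance by penalized least squares, selection of
    optimal 1-, 2- and 3-point limited sampling designs by a
    mean-square-error criterion, non-compartmental clearance with
    Bland-Altman agreement statistics, and a Laplace-approximate
    nonlinear mixed-effects estimator of the population parameters.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
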