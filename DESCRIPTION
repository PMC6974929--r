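Package: arsdhapk
Title: Population Pharmacokinetics of Artesunate and Dihydroartemisinin in Pregnancy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous drug-metabolite population pharmacokinetic analysis of
    oral artesunate and its active metabolite dihydroartemisinin in pregnant and
    non-pregnant malaria patients. Implements a transit-compartment absorption
    model with one-compartment disposition for parent and metabolite, Laplacian
    nonlinear mixed-effects estimation with the M3 censored-data likelihood for
    observations below the limit of quantification, allometric and linear
    covariate models, stepwise and full covariate analyses, stratified
    nonparametric bootstrap, prediction-corrected visual predictive checks, and
    a synthetic-study generator emulating the trial design together with paired
    pregnancy-impact exposure simulations.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
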