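Package: busulfanpk
Title: Population Pharmacokinetics of Twice-Daily Intravenous Busulfan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-pharmacokinetic analysis of twice-daily
    intravenous busulfan in pediatric hematopoietic stem cell transplantation.
    Implements a one-compartment multi-infusion structural model with an
    exponentially time-varying elimination rate constant, body-size and
    maturation covariate functions, non-compartmental exposure estimation
    (AUC, AUMC, MRT), a stochastic approximation EM (SAEM) engine for
    nonlinear mixed-effects estimation with importance-sampling likelihood,
    stepwise covariate model building, model diagnostics (icwres, npde,
    visual predictive checks, bootstrap), and a synthetic cohort generator
    emulating a therapeutic-drug-monitoring study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
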