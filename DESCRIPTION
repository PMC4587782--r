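Package: epidistance
Title: Adaptive Social Distancing Epidemics on a Square Lattice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based SIR epidemics on a bounded square lattice in
    which susceptible individuals spontaneously reduce their contact radius in
    response to the locally observed infection load, governed by a personal
    risk attitude. Provides the risk-attitude response curve and its exact
    inversion, a nested random-effects population model of log risk attitude
    (participant, game and time variance components), a synthetic
    participatory-game generator that emulates a focal player inside the
    simulation, an inference pipeline from gameplay traces to risk attitudes
    with model-fit diagnostics (MAPE), maximum-likelihood fitting and AIC
    comparison of the nested variance-component models, and experiment drivers
    for baseline-risk-attitude sweeps, no-response baselines and local
    sensitivity analyses of the transmission and recovery probabilities.
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
    lme4,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
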