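Package: tritea
Title: Temperature-Dependent Tritrophic Dynamics of Tea Plants, Green
    Leafhoppers and Their Natural Enemies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulator for the stage-structured tritrophic system of tea
    crops, tea green leafhoppers (Empoasca onukii; eggs, nymphs, adults)
    and their natural enemies (egg parasitoids or predators).  Provides
    the deterministic limit-cycle model with Holling type II feeding and
    parasitism, temperature-dependent rates (Gaussian crop growth factor,
    Arrhenius stage durations, developmental thresholds), a Poisson
    tau-leap stochastic engine driven by daily temperature series, a
    synthetic humid-subtropical climate generator, outbreak timing and
    effective accumulated temperature (EAT) statistics, local sensitivity
    analysis, and slow-release semiochemical biocontrol experiments
    (attractant and repellent modes) with start-time optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
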