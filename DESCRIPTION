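Package: traitscreen
Title: Trait Screening for Wheat Crop Models with Morris Global Sensitivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens crop-model parameters ("component traits") for their
    impact on wheat yield across a target population of environments.
    Implements the Morris elementary-effects method (6-level one-at-a-time
    trajectories with space-filling selection and meta-parameter groups), a
    parameter registry with fixed-width variation-range rules, a surrogate
    daily wheat growth model (thermal-time phenology with photoperiod and
    vernalisation, radiation- and transpiration-limited biomass accumulation,
    a layered soil water bucket and a simple nitrogen pool), a stochastic
    weather generator for Australian site archetypes, and downstream analysis:
    impact classification, Ward clustering of trait-by-output impacts,
    eta-squared variance decomposition of trait impacts across management
    factors, drought environment typing and stress-index regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
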