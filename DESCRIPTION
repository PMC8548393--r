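Package: coexar
Title: Coexistence-Area Relationships from Neighborhood Interaction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bottom-up construction of species-area (SAR) and
    coexistence-area (CAR) relationships for annual plant communities.
    Infers Ricker fecundity models with negative-binomial noise from
    focal-individual neighborhood observations, transforms the fitted
    intrinsic fecundities and interaction matrices to an equivalent
    Lotka-Volterra frame via seed-bank vital rates, decides feasibility
    and local stability of every species subset, classifies each species
    into dominant, pair, multispecies or transient persistence
    categories, averages richness and persistence over all plot
    combinations to build SAR and CAR curves with power-law fits, and
    compares observed curves against interaction-reshuffling null
    models. Includes a synthetic-community generator that emulates the
    gradient-structured field design the analysis assumes, so the whole
    pipeline is testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    dplyr,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
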