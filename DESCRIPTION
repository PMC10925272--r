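Package: voltaxis
Title: Continuum Modelling of Spatially Heterogeneous Collective Electrotaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models the spatially heterogeneous response of epithelial
    monolayers to direct-current electric fields (collective electrotaxis).
    Provides an adaptation-excitation model of the intracellular field
    signal, a four-region force-balance model of tissue velocities,
    adaptive-covariance Markov chain Monte Carlo calibration with
    convergence diagnostics and posterior-predictive bands, a conservative
    finite-volume solver for a density-dependent reaction-advection-diffusion
    model of the migrating monolayer in one and two dimensions, geometry and
    size sweeps of the induced velocity field, and design of electric fields
    (closed-form one-dimensional potentials and a fixed-magnitude
    two-dimensional heuristic) that drive a prescribed tissue velocity.
    Includes seeded generators for synthetic velocity traces, density
    profiles and nuclei point clouds emulating the structure of published
    monolayer electrotaxis experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
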