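Package: ecoevoclim
Title: Eco-Evolutionary Metacommunity Dynamics Under Climate Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially explicit eco-evolutionary simulator for communities of
    resource and consumer species along a warming latitudinal gradient.
    Couples quantitative-genetic evolution of species' temperature optima
    with Lotka-Volterra competition (constant or declining with trait
    distance), Holling type II trophic interactions, and nearest-neighbour
    dispersal over a patch chain. Provides the climate forcing, closed-form
    phenotype integrals, a fast compiled right-hand side, a replicate runner
    with extinction handling and low-density genetic-variance regulation, a
    16-scenario factorial experiment driver, and community metrics (local
    and regional richness, range breadth, Bray-Curtis turnover, global
    losses, community-weighted trait lag and dispersion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
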