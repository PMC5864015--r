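Package: graztox
Title: Agent-Based Simulation of Cattle Grazing Pastures with Toxic Larkspur
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Spatially explicit, behavior-based agent-based model of cattle
    grazing a pasture containing toxic Geyer's larkspur (Delphinium geyeri).
    Generates synthetic pasture landscapes (spatially correlated forage,
    clustered larkspur point process, stream water feature), simulates
    individual cow foraging, herding, watering and site-change behavior with
    a daily toxicokinetic threshold model of MSAL-alkaloid poisoning, runs
    full factorial herd-cohesion x stocking-density experiments, and provides
    the accompanying statistical layer: negative-binomial and Poisson count
    GLMs with AICc model screening, standardized-beta influence comparison,
    and mechanism regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
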