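Package: nicherange
Title: Climatic Niche Evolution and Time-Stratified Range Evolution on Dated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of climatic niches and geographic
    ranges on time-calibrated phylogenies. Fits Brownian motion,
    Ornstein-Uhlenbeck, white-noise and Pagel's lambda models of continuous
    trait evolution with AIC-weight model comparison and likelihood-ratio
    tests of phylogenetic signal; reconstructs ancestral states under
    Brownian motion with confidence intervals, traitgram coordinates and
    propagation of niche-model uncertainty via predicted niche occupancy
    (PNO) profiles; computes PNO profiles from paired suitability and
    climate grids; fits time-stratified dispersal-extinction-cladogenesis
    style models of discrete range evolution (DEC, DIVALIKE, BAYAREALIKE,
    each with and without founder-event speciation) and summarises
    biogeographic stochastic mappings by event type. Includes forward
    simulators for traits and range histories and a worked 13-taxon
    Andean-plant example data set.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
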