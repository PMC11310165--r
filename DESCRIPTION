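Package: soilassembly
Title: Community Assembly Processes, Multifunctionality and Co-Occurrence
    Networks for Seasonal Soil Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of seasonal soil microbiome surveys in a
    factorial plantation-by-season design. Implements phylogenetic null-model
    inference of community assembly (beta mean nearest taxon distance, the
    beta nearest taxon index, abundance-based Raup-Crick dissimilarity, and
    the five-way partition into variable selection, homogeneous selection,
    dispersal limitation, homogenizing dispersal and undominated processes),
    soil multifunctionality indices from z-score standardised attribute
    panels, eco-enzymatic stoichiometry ratios, high-throughput qPCR
    functional-gene (QMEC) filtering, protist trophic profiling, alpha and
    beta diversity with PERMANOVA, and Spearman co-occurrence network
    topology. A seeded synthetic-data generator emulates the study design
    under controllable assembly regimes so every stage is testable without
    sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    picante,
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
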