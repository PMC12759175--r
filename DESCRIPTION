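Package: riverfrag
Title: River Network Connectivity, Habitat Suitability Weighting, and
    Barrier Prioritization for Fish
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Graph-based longitudinal connectivity analysis for dendritic
    river networks fragmented by dams and waterfalls. Represents a river
    basin as a forest of reaches joined by confluences and barriers,
    computes the Reach Connectivity Index (RCI) from direction-specific
    cumulative barrier passabilities, integrates it with climatic habitat
    suitability of fish species groups (RCIsuit), aggregates it to the
    Catchment Connectivity Index (CCI), and ranks barriers by the
    connectivity gained if each were removed or never built (dCCI,
    leave-one-out). Includes consensus rules for ensemble species
    distribution model outputs (AUC filtering, max sensitivity+specificity
    thresholding, majority vote, group means), a passability sensitivity
    analysis, and a seeded generator of synthetic dendritic riverscapes
    with barrier portfolios and autocorrelated suitability layers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
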