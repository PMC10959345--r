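Package: jagconn
Title: Habitat Connectivity and Priority-Area Classification for Jaguar Conservation Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end landscape-connectivity pipeline for identifying
    priority conservation and recovery areas for the jaguar (Panthera onca).
    Implements occurrence-record reliability classification and spatial
    thinning, minimum-training-presence binarization of continuous habitat
    suitability with elevation refinement, connected-component extraction of
    remnant habitat patches, distance-capped least-cost corridors over a
    human-footprint resistance surface, current-flow betweenness centrality
    of the patch network, and a four-criterion prioritization that classifies
    patches into conservation (JPCA I/II) and recovery (JPRA I/II) classes.
    Ships a seeded synthetic-landscape generator so the whole pipeline is
    testable without external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    geosphere,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
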