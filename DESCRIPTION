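Package: prionet
Title: Tissue-Specific Protein Interaction Networks and Network-Propagation
    Candidate Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds tissue- and condition-specific protein-protein interaction
    (PPI) networks from a scored interactome (filtering to a measured protein
    universe, adding stimulus proteins and their neighbours, and connecting
    components through shortest paths), scores seed proteins from secretome
    concentrations (replicate averaging, min-max scaling, stimulus forcing) or
    as binary indicators, propagates seed scores by hop-limited message
    passing in the NetScore style, selects and compares top-k% candidate
    proteins across conditions, and characterizes networks (average degree,
    clustering, density, Louvain modularity, diameter). Ships a synthetic-data
    module generating planted-community interactomes, secretome panels and
    mass-spectrometry-style protein universes with known ground truth, so the
    whole pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
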