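Package: kgsketch
Title: Schematic Subgraph Extraction from Biomedical Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns a short list of biological concept labels and desired
    source-target connections into a Cytoscape-ready schematic subgraph of a
    biomedical knowledge graph. Concept labels are indexed to graph nodes by
    substring and fuzzy matching, all tied shortest paths between each pair
    are enumerated by breadth-first search over the undirected view of the
    triples, and paths are ranked by semantic graphical actions: path-degree
    product (hub avoidance), node2vec cosine similarity to the target, and
    edge-class inclusion/exclusion constraints. Extracted subgraphs can be
    augmented with category-filtered nearest neighbors (for example drugs
    targeting pathway proteins) and written as GraphML, SIF and attribute
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
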