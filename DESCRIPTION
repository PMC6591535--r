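Package: seqsimnet
Title: Sequence Similarity Networks from Pairwise E-Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build protein sequence similarity networks from directed pairwise
    alignment E-values, cluster them into nested resolution levels by
    minimum-span clustering, classify query sequences against a base set by a
    minimum-distance threshold with an optional remote-homology fallback, and
    analyze the resulting weighted graphs with four centrality measures
    (weighted degree, closeness, betweenness, eigenvector) plus edge
    betweenness. Includes seeded synthetic generators with planted hierarchical
    structure for offline benchmarking, exporters for GraphML, Cytoscape.js
    JSON and edge-list TSV, and a deterministic end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    xml2,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    mclust,
    pROC,
    optparse
Config/testthat/edition: 3
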