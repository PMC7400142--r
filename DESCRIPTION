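Package: fcmpanel
Title: Consensus Fuzzy Cognitive Maps from Multi-Expert Rating Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building semi-quantitative system models (fuzzy
    cognitive maps) from structured expert elicitation. Raw workshop
    factors are consolidated into a main-factor set; per-expert 0-10
    influence ratings are aggregated into a weighted directed graph with
    a quorum-and-mean consensus rule; degree, weighted-degree and motif
    statistics summarise the network; what-if scenarios are propagated
    through the map with a logistic squashing update; and a seeded
    synthetic panel generator benchmarks how well the consensus rule
    recovers a known ground-truth model from noisy ratings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    yaml,
    xml2,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
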