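Package: guildnet
Title: Network-Based Disease-Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genome-wide prioritization of candidate disease genes on
    protein-protein interaction networks by guilt-by-association. Implements
    four network-topology scoring algorithms (NetShort, NetZcore, NetScore
    and their consensus NetCombo) together with four widely used global
    topology baselines (random walk with restart, PageRank with priors,
    network propagation and functional flow), degree-preserving score
    randomization, a balanced cross-validation evaluation protocol with
    ROC AUC and top-rank sensitivity, seed-connectivity statistics, and a
    generator of synthetic scale-free interactomes with planted seed modules
    so the whole workflow runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
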