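Package: lncrwr
Title: Ranking lncRNA-Disease Associations by Network Diffusion on
    Tripartite Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts and ranks long non-coding RNA (lncRNA) associations
    with diseases by random walk with restart over a tripartite
    lncRNA-protein-disease interaction network. For each disease a local
    subnetwork is extracted (seed genes, their first protein-protein
    interaction neighbours, and the lncRNAs attached to those proteins),
    a restart-biased walker is diffused to its steady state, and lncRNAs
    are ranked by steady-state probability. Results across diseases are
    collapsed into a weighted bipartite lncRNA-disease network, which can
    be evaluated by ROC/AUC against validated associations, with a
    node-label-shuffled null model and rank-sum comparisons. Includes a
    synthetic benchmark generator with planted disease modules so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
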