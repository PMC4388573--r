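Package: miregnet
Title: Disease-Specific miRNA-Target Regulatory Networks from Literature,
    Expression and Protein Interactions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs and ranks disease-specific microRNA-target regulatory
    networks. Genes are seeded from the literature by a hypergeometric
    disease score on per-gene publication counts against a disease corpus;
    sequence-based miRNA-target predictions are filtered by significant
    negative Pearson correlation of paired expression profiles; the network
    is expanded over a protein-protein interaction graph and new targets are
    admitted by a guilt-by-association rule gated on Gene Ontology
    background-function enrichment with Benjamini-Hochberg control; finally a
    triangle-based regulatory subnetwork is extracted around every node and
    subnetworks are ranked by a Fisher-combined enrichment score together
    with power-iteration eigenvector centrality on a subnetwork meta-network.
    A deterministic synthetic-data generator with planted signal supports
    fully offline validation, and a command-line driver runs the whole
    pipeline from plain tab-separated inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
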