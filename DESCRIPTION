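Package: rspnet
Title: miRNA Target-Specific Regulatory Sub-Pathway Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Enumerates miRNA target-specific regulatory sub-pathways
    (two-hop paths T-G1-G2) from a protein-protein interaction graph,
    scores each sub-pathway with Jaccard similarity over Gene Ontology
    annotation sets and an exact hypergeometric overlap p-value, assembles
    disease- and tissue-specific miRNA-protein regulatory networks with
    interaction-closure edges, and computes comorbid gene sets for
    disease pairs. Includes a seeded synthetic-fixture generator with a
    manifest of planted ground truth, command-line entry points, and
    exporters to TSV, SIF, GraphML and JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
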