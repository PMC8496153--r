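Package: umgnet
Title: Upward-Mobility Gene Prioritization by Network Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes rarely mutated long-tail cancer genes by propagating
    quantized somatic-mutation scores over filtered protein-protein
    interaction networks with a random-walk-with-restart kernel. Genes whose
    rank rises by at least a cohort-specific fraction of the gene universe
    into the top post-propagation ranks are flagged as upward-mobility genes,
    optionally filtered by cell-line dependency evidence, intersected across
    networks, and categorized by their adjacency to stratified known driver
    genes. Includes rank-enrichment validation statistics, a percentage-based
    cell-line impact score, and a seeded synthetic-cohort generator with
    planted structure for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
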