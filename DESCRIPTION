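Package: pathneighbor
Title: First-Neighbor Interaction Subnetworks and Signaling Pathway
    Overrepresentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves protein, gene and drug query terms to canonical
    accessions, extracts the first-neighbor subnetwork of the queries from
    multi-source protein-protein and genetic interaction data, annotates
    signaling-pathway memberships, and scores per-pathway overrepresentation
    of the displayed proteins with an upper-tail hypergeometric test and
    Benjamini-Hochberg false discovery rate control. Ships strict readers
    and writers for a normalized interaction edge-list dialect, GMT gene
    sets, identifier-synonym and drug-target tables, and JSON, plain-text,
    SIF and GraphML reports, together with packaged case-study fixtures, a
    seeded synthetic network generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
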