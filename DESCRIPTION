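Package: dlrecon
Title: Duplication-Loss Reconciliation of Gene Trees with Species Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parsimony reconciliation of a binary gene tree with a rooted
    binary phylogenetic species network under the duplication-loss model.
    Implements two problems: finding the displayed tree (switching) of the
    network that minimises the classical duplication-loss reconciliation
    cost, solved independently per biconnected component so the work is
    exponential only in the network level, and finding a minimum-cost
    reconciliation against the whole network by dynamic programming over
    candidate mapping sets, polynomial in the number of hybridization
    nodes. Includes extended-Newick input/output, a random network and
    gene-family simulator with known event counts, and brute-force
    oracles used by the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
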