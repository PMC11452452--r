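Package: netdiv
Title: Phylogenetic Subnet Diversity on Rooted Phylogenetic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the rooted Phylogenetic Subnet Diversity (rPSD, also
    known as AllPaths-PD) of leaf subsets of weighted rooted phylogenetic
    networks, and finds rPSD-optimal subsets of every cardinality.  Reads and
    writes extended Newick (hybrid-node convention) and edge-list formats,
    classifies networks by level and reticulation arity via biconnected
    (blob) decomposition, enumerates the exchange-pair families within which
    an improving leaf swap is guaranteed, and implements exact greedy
    optimizers for phylogenetic trees, galled trees, semibinary level-2
    networks and semi-3-ary level-1 networks, together with brute-force
    oracles, seeded random network generators, and an empirical gap-scan
    harness for network classes where no greedy algorithm is known.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
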