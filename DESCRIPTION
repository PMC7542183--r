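Package: kbinv
Title: Weighted Genome Inversion Distances via Confluent Rewriting Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact minimal weighted inversion distances between genome
    arrangements, computed by completing group presentations of inversion
    models into confluent string-rewriting systems with the Knuth-Bendix
    procedure under a weighted lexicographic reduction order.  Includes
    permutation arithmetic for unsigned inversion operators, the linear
    all-inversions model with length-proportional weights and the circular
    adjacent-inversion model, an independent shortest-path oracle on the
    weighted Cayley graph, dihedral symmetry quotients for circular
    genomes, and distance-matrix to neighbor-joining phylogeny output
    (PHYLIP and Newick formats).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    ape,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
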