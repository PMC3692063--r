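Package: orthoscan
Title: Phylogenetic Placement of Protein Queries with Subtree Profile HMMs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Places a query protein into pre-built gene-family phylogenies by
    scoring profile hidden Markov models built at every node of each family
    tree, resolves an orthology-supported enclosing clade around the
    top-scoring node, extracts and filters candidate orthologs with pairwise
    alignment criteria, and derives a weighted consensus functional annotation
    from the accepted orthologs. Orthology structure on the tree is inferred by
    identity-threshold tree partitioning (Kerf cuts), species-overlap
    duplication inference with super-ortholog (tree-distance-zero) groups, and
    subtree bracketing of third-party orthology labels. Ships a seeded gene
    family simulator with known orthology ground truth and a leave-one-out
    placement benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
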