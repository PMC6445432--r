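Package: rogueplot
Title: Rogue Taxon Placement Probabilities on Consensus Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes and draws the posterior probability that a rogue taxon
    (typically an incompletely preserved fossil) attaches to each branch of a
    consensus tree built from a sample of phylogenies, with probability mass on
    branches absent from the consensus collapsed onto the most recent common
    ancestor (MRCA) node, so that the displayed attachment probabilities always
    sum to one. Reads Newick and NEXUS (MrBayes '.t' dialect) tree files with
    burn-in removal and even subsampling, builds strict-majority consensus
    trees with clade supports, and renders the result as a rectangular
    phylogram in SVG in which branches parallel to the tree direction are
    coloured by direct-attachment probability and perpendicular connectors by
    MRCA-bucket probability. Also prepares NEXUS standard-datatype
    morphological matrices for Bayesian analysis: gap weighting of continuous
    characters into ordered discrete states, liberal or conservative recoding
    of questionable scores, state-space expansion against a reference, taxon
    coverage statistics, and emission of MrBayes command blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
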