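Package: fishsteiner
Title: Rectilinear Steiner Tree Heuristics for Tumor Phylogenies from FISH
    Copy Number Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs tumor progression trees from multi-probe
    fluorescence in situ hybridization (FISH) gene copy number counts.
    Models progression as a rectilinear Steiner minimum tree (RSMT) over
    cell count patterns under the L1 metric and provides two heuristics:
    iterative median (Steiner node) insertion starting from the minimum
    spanning tree, and Wagner-parsimony tree search followed by interval
    dynamic programming that labels internal nodes, lifts leaves and
    contracts trivial branches. A generalized metric with unit-cost
    chromosomal and whole-genome duplication events extends the heuristics
    to the duplication Steiner minimum tree (DSMT) problem. Includes an
    exact small-instance solver (Hanan grid with the Dreyfus-Wagner
    dynamic program), a tumor-growth simulator with ground truth, and
    TSV/Newick/JSON input and output plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    phangorn,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
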