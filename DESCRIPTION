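Package: gcnscreen
Title: Graph Convolutional Screening of Combinatorial Enzyme Variant Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a spectral graph convolutional regressor on small labeled
    combinatorial mutant libraries of an enzyme binding site and uses it to
    screen the full combinatorial sequence space for variants with favourable
    predicted binding energies.  The binding site is represented as a fixed
    residue graph with inverse C-alpha-distance edge weights and AAindex-style
    physicochemical node features that change with the variant sequence.  The
    model stacks a graph-convolution-with-skip layer, MinCut-style soft graph
    pooling and a dense readout, trained with Adam and early stopping.  A
    seeded epistatic fitness-landscape simulator provides ground-truth labels
    for development and testing, and a sequence-embedding fusion head can
    combine the graph model with per-sequence embedding matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    bio3d,
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
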