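Package: aavchimera
Title: Barcode-Swap Chimerism Analysis for Pool-Packaged AAV Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify chimerism (barcode swapping) in complex
    adeno-associated virus (AAV) libraries packaged as a pool. Builds a
    validated dictionary of unique dual-barcode (BC1-BC2) pairs from
    short-read association data with abundance classification, artifact
    filtering and Levenshtein-graph error correction; parses nanopore
    long reads of barcoded cargoes via signpost-anchored local alignment
    with layout validation, demultiplexing and exact dictionary matching;
    tallies concordant versus discordant barcode pairs with bootstrap
    false-discovery-rate comparisons and stratified Fisher's exact tests;
    annotates insert alignments (simple, composite, unmapped) and calls
    pairwise insert homology against a shuffled null; and simulates
    chimeric packaged libraries with known ground truth so every stage is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    igraph,
    data.table,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, QualityControl, GeneTherapy
RoxygenNote: 7.3.3
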