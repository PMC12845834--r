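Package: attnfold
Title: Attention-Based RNA Secondary Structure Prediction via Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts RNA secondary structure, including pseudoknots, by
    mapping a nucleotide sequence to a binary base-pair contact map. A
    multi-head self-attention encoder turns the sequence into a pairwise
    correlation map, a small U-Net style refiner sharpens it into a
    probability-like contact score map, and a constraint-enforcing
    Lagrangian decoder converts scores into a valid structure (symmetry,
    pairing exclusivity, minimum loop length). Includes readers and
    writers for FASTA, CT, BPSEQ and layered dot-bracket formats, a
    synthetic generator of hairpin, cloverleaf and H-type pseudoknot
    sequence/structure pairs for testing and desk-scale training, full
    gradient-based training of the encoder and refiner, and base-pair
    precision/recall/F1 evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
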