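Package: titan
Title: Bimodal Attention Networks for T-Cell Receptor - Epitope Binding Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binding between T-cell receptor (TCR) beta-chain sequences
    and antigenic peptides (epitopes). Implements a bimodal neural network that
    encodes the TCR stream with BLOSUM62 (or biophysical or learned) amino-acid
    embeddings and the epitope stream either as amino acids or atom-level SMILES,
    fuses the two streams with convolutions and context attention, and outputs a
    binding probability. Also provides a length-normalized Levenshtein k-nearest-
    neighbour baseline, dataset curation and negative sampling by shuffling,
    TCR-disjoint and strictly disjoint cross-validation splits, peptide-to-SMILES
    conversion with randomized-SMILES augmentation, attention-heatmap extraction
    with variance statistics and epitope-compression analysis, and a synthetic
    repertoire generator with a planted binding rule for desk-scale benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    ChemmineOB,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    pROC,
    optparse
Config/testthat/edition: 3
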