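Package: rgenecap
Title: Plant Resistance Gene Classification and Capture Probe Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies protein sequences into four plant resistance-gene
    families (TNL, CNL, RLK, RLP) with one-vs-rest support vector machines
    trained on sequence-compositional feature vectors (amino acid, dipeptide,
    tripeptide, multiplet, charge and hydrophobicity composition), selected by
    kernel grid search with stratified 5-fold cross-validation and the
    Matthews correlation coefficient. Designs hybridization-capture probes by
    tiling, filtering and deduplicating the nucleotide sequences of predicted
    R-genes, and extracts open reading frames from transcripts so the whole
    workflow runs from either protein or transcript FASTA input. Includes a
    synthetic labeled-sequence generator for end-to-end testing, dataset
    curation from domain annotations with greedy redundancy clustering, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    Matrix,
    methods,
    stats,
    tools,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
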