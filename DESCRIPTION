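Package: scXmatch
Title: Cross-Species Cell Type Matching from Protein Embeddings and Transfer Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Matches cell types between single-cell RNA-seq datasets from two
    species. Genes are paired across species from protein-embedding cosine
    distances or BLAST tabular output, a shared feature space spanning both
    species' matched genes is built by weighted-average imputation over the
    gene-match graph, a shared-weight two-layer cell-embedding network with
    per-species softmax classifiers is trained under a composite loss
    (class-weighted label-smoothed cross-entropy, a cross-species alignment
    term, and L2 regularisation), and labels are transferred by classifier
    swapping. Matches are scored with combined confusion matrices, the average
    diagonal score (ADS), and recall against a ground-truth correspondence.
    Includes a paired-species synthetic data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
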