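Package: ncis
Title: Network-Assisted Co-Clustering for Cancer Subtype Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cancer subtypes from gene expression by combining a
    directed gene-interaction network with a weighted co-clustering model.
    Genes are first weighted by propagating their expression variability
    (normalized median absolute deviation) over the network with a modified
    PageRank scheme; the weighted expression matrix is then factorized by a
    semi-nonnegative matrix tri-factorization that simultaneously clusters
    samples into subtypes and genes into co-expression groups. Cluster numbers
    are chosen by consensus matrices over repeated random initializations and
    their cophenetic correlation. Includes a network-driven expression
    simulator with permuted "noisy" genes and evaluation utilities
    (optimal-matching clustering accuracy, per-gene ANOVA ranking,
    top-shared-gene selection).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
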