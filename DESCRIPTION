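Package: aracnekit
Title: Gene Regulatory Network Inference by Adaptive-Partitioning Mutual
    Information
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reverse engineering of transcriptional regulatory networks from
    gene expression matrices in the ARACNE family. Pairwise dependence
    between transcription factors and candidate target genes is scored with
    an adaptive-partitioning mutual information estimator driven by a
    breadth-first queue over rank-space rectangles; candidate edges are
    thresholded against a permutation null model, pruned with the data
    processing inequality on every TF-TF-target triangle, and optionally
    consolidated across bootstrap resamples with a Poisson occurrence model
    and Bonferroni correction. Ships a seeded synthetic regulatory-network
    generator for end-to-end validation and a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
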