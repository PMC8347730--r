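Package: crossmotif
Title: Cross-Family Protein Sequence Motif Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether unrelated protein families share any
    sequence motif. Provides a synthetic family generator (diverged
    homologues with optionally planted, degradable motifs), k-mer
    dissimilarities with diversity-preserving reduction of a family to a
    fixed number of representatives, neighbor-joining trees and progressive
    profile alignment, per-column Shannon-entropy conservation profiles with
    reference-coordinate masking and degenerate consensus patterns, ZOOPS
    expectation-maximization motif discovery with permutation-based
    empirical E-values, and cross-family shared-motif searches with
    sliding-window comparison of per-family motif sets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    Matrix,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
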