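Package: panvhh
Title: Analysis of Nanobody (VHH) Phage-Display Panning NGS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for next-generation sequencing of nanobody
    (VHH) phage-display panning campaigns: overlap-based merging of paired
    amplicon reads, error-tolerant V-gene and CDR3 annotation by approximate
    string matching, CDR3-level clone collapsing with counts-per-million
    normalisation, pseudocounted log fold-change enrichment calls, greedy
    identity clustering of enriched CDR3s, BLOSUM62 all-vs-all alignment with
    MDS embedding and cladograms, ranked top-candidate selection with
    replicate awareness, cross-pan overlap and subtraction, and a built-in
    panning simulator with known ground truth for validation. All user-facing
    functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    rlang,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    ggplot2,
    jsonlite,
    generics,
    withr,
    stats,
    utils,
    ape,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    yaml
Config/testthat/edition: 3
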