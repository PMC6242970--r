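Package: dualcut
Title: Repair-Outcome Analysis for Dual-Cas9 Segmental Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the editing outcomes of paired CRISPR-Cas9
    nucleases that cut a locus at two neighbouring positions. Classifies
    amplicon deep-sequencing reads into seven repair-outcome classes
    (unedited, indels at either or both cut sites, precise and imprecise
    segmental deletions, and inversions) by affine-gap global alignment
    against candidate references built from the two predicted cut junctions;
    collapses PCR duplicates with unique molecular identifiers (UMIs) using a
    minimum-support consensus rule; converts lesion counts to rates with
    triplicate negative-control background subtraction, precise-deletion
    fractions, logit and Benjamini-Hochberg helpers, and GUIDE-seq
    specificity-ratio summaries; enumerates composite dual-PAM target sites
    (SpCas9 paired with SaCas9 or NmCas9) genome-wide under canonical or
    expanded PAM rules; and simulates reads, UMI libraries, and genomes with
    planted composite sites so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    methods,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
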