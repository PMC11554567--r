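Package: dvrscan
Title: Detection and Characterisation of Differential RNA Variants from
    Replicated Allele Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical calling of condition-dependent RNA editing sites
    (differential variants in RNA, DVRs) from replicated per-site allele
    counts, using a beta-binomial likelihood-ratio test with genomic-SNV
    subtraction, followed by characterisation of the called sites: RNA
    secondary-structure context via a built-in minimum-free-energy folding
    engine, sequence-motif enrichment (IUPAC patterns and position frequency
    matrices), editing-activity selectivity (Lorenz curves and Gini
    coefficients), and strand-aware eCLIP fold-enrichment metaprofiles.
    Includes a fully deterministic synthetic-study generator with truth
    tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
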