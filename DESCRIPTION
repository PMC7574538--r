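Package: sceditr
Title: Single-Cell CRISPR Edit Detection from Droplet Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for quantifying CRISPR-Cas9 editing in droplet-based
    single-cell targeted amplicon sequencing. Extracts composite cell barcodes
    from raw reads, calls cells by read count, assigns reads to panel amplicons
    with a semi-global affine-gap aligner, classifies per-read modification
    inside a narrow quantification window around the predicted cleavage site,
    summarizes per-cell allele tables and zygosity (WT/WT, WT/Mut, Mut/Mut,
    Mut/Mut2), flags doublets in cell-line admixtures, tabulates multi-gene
    edit co-occurrence, and calls sgRNA presence from single-cell qPCR Cq
    matrices. Includes a synthetic droplet-read simulator with full ground
    truth (genotype mixtures, allelic dropout, doublets, sequencing error) so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    Matrix,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
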