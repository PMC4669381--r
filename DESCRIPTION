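Package: uindel
Title: Analysis of Uridine Insertion/Deletion RNA Editing from RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying uridine insertion/deletion (U-indel) RNA
    editing in kinetoplastid mitochondria from deep sequencing data.
    Provides an editing-aware local aligner (Smith-Waterman with
    nucleotide-specific gap penalties) that maps reads carrying arbitrary
    U-indels onto pre-edited cryptogene references, reconstruction of the
    mature edited mRNA by following the 3'-to-5' progression of editing,
    classification of reads as pre-edited, main-pathway or alternatively
    edited ("misedited"), merging of alternative reads into editing
    intermediates with fractional support values, editing statistics and
    edited-ORF translation, a wobble-aware search for candidate guide-RNA
    genes in genomic contigs, and a fully reproducible simulator of
    cryptogenes, gRNA-block editing cascades and read populations that
    serves as the ground-truth test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    jsonlite,
    ggplot2,
    generics,
    optparse,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
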