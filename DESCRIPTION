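Package: ficcseq
Title: Single-Nucleotide Mapping of RNA Modification Sites from
    Truncation-Based Crosslinking Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for enzyme-specified mapping of RNA
    modification target sites from truncation-based crosslinking
    sequencing libraries (FICC-Seq, miCLIP, UV iCLIP). Includes in-line
    barcode demultiplexing and UMI-based PCR-duplicate collapsing,
    single-nucleotide crosslink extraction from read 5' truncation
    positions, permutation-based FDR calling of significant sites, peak
    clustering with local-maxima refinement and replicate merging,
    size-factor normalisation and replicate correlation, a structural
    consensus coordinate system for mature tRNAs with metagene
    projection and catalytic +1 methylated-base inference, anchored
    k-mer motif discovery against dinucleotide-preserving shuffles, and
    a fully synthetic read simulator with ground truth so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
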