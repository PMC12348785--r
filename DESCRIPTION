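Package: rddmscan
Title: Integrative Methylome, Small RNA and Transcriptome Analysis for
    RdDM Locus Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the integrative analysis of whole-genome bisulfite
    sequencing, small RNA sequencing and RNA sequencing in a treatment
    time course, aimed at loci regulated through RNA-directed DNA
    methylation (RdDM). Computes per-context (CG/CHG/CHH) cytosine
    methylation levels, calls differentially methylated regions with a
    Fisher-exact filter cascade (FDR, coverage, level difference and fold
    change), quantifies 24-nt siRNA clusters and their differential
    regulation, calls differentially expressed genes, associates DMRs
    with sRNA clusters by odds ratios, maps DMRs onto strand-aware
    promoters, and screens for candidate RdDM-regulated genes (promoter
    TE, CHH hypomethylation, reduced 24-nt siRNAs, increased expression).
    Includes a coupled tri-omics simulator with planted ground truth for
    end-to-end validation, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
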