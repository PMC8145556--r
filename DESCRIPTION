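Package: isoqc
Title: Quality Control and Contamination Detection for Microbial Isolate
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembly-based quality assessment for bacterial whole-genome
    sequencing of isolates. Computes read-level (Q30 fraction, coverage depth)
    and assembly-level (contig count, N50, GC content, duplication ratio)
    quality metrics, performs k-mer based taxonomic classification of reads and
    contigs, MinHash sketch reference selection, MLST and core-genome allele
    calling with allele-distance relatedness categories, and read-level
    detection of intragenus contamination via contaminating single-nucleotide
    variants in core genes. A species-specific threshold engine derives
    quantile-based pass/warning/fail ranges and aggregates all metrics into a
    traffic-light verdict with a structured two-branch JSON report. Includes an
    in-silico contamination simulator and a sensitivity benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    stringi,
    readr,
    rlang,
    jsonlite,
    generics,
    ggplot2,
    withr,
    stats,
    tools,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
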