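# Read-level quality metrics feeding the QC decision.

#' Mask low-quality bases as N
#'
#' Replaces every base below `min_qual` with N, leaving qualities untouched.
#' Intended for downstream k-mer work (classification, baiting) on very noisy
#' data; the quality statistics themselves are always computed on the
#' unmasked input.
#'
#' @param reads read tibble with qualities.
#' @param min_qual Phred threshold below which bases are masked.
#' @return the read tibble with masked sequences.
#' @export
mask_low_qual <- function(reads, min_qual = 5L) {
  check_seq_tbl(reads, need_qual = TRUE)
  cut <- intToUtf8(33L + as.integer(min_qual))
  reads$seq <- mapply(function(s, q) {
    low <- which(strsplit(q, "")[[1]] < cut)
    if (!length(low)) return(s)
    v <- strsplit(s, "")[[1]]
    v[low] <- "N"
    paste(v, collapse = "")
  }, reads$seq, reads$qual, USE.NAMES = FALSE)
  reads
}

#' Read-level quality statistics
#'
#' Computes the read count, base count, Q30 base fraction (proportion of bases
#' with Phred quality >= 30) and the estimated coverage depth
#' `n_bases / genome_length`. No trimming is applied: metrics describe the
#' input reads as-is. The coverage denominator should be the sample's assembly
#' length when one exists, otherwise an expected genome length for the taxon.
#'
#' @param reads a read tibble with per-base qualities (`id`, `seq`, `qual`).
#' @param genome_length positive denominator for the coverage estimate, in bp.
#' @param q_threshold Phred threshold for the high-quality base fraction.
#' @return a one-row tibble: `n_reads`, `n_bases`, `q30_fraction`,
#'   `est_coverage`.
#' @export
compute_read_stats <- function(reads, genome_length, q_threshold = 30L) {
  check_seq_tbl(reads, need_qual = TRUE)
  if (!length(genome_length) == 1 ||
      (!is.na(genome_length) && (!is.numeric(genome_length) || genome_length <= 0))) {
    stop("`genome_length` must be a single positive number (or NA when unknown)",
         call. = FALSE)
  }
  if (nrow(reads) == 0) stop("no reads supplied", call. = FALSE)
  qc <- cpp_qual_counts(reads$qual, as.integer(q_threshold))
  n_bases <- sum(nchar(reads$seq))
  if (qc[[2]] != n_bases) {
    stop("sequence and quality lengths disagree", call. = FALSE)
  }
  tibble::tibble(
    n_reads = nrow(reads),
    n_bases = n_bases,
    q30_fraction = qc[[1]] / qc[[2]],
    est_coverage = n_bases / genome_length
  )
}
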