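# Assembly statistics, sketch-based reference selection, contig-to-reference
# anchoring, duplication ratio and genome fraction.

#' Assembly statistics
#'
#' Contigs shorter than `min_contig_len` are removed before anything is
#' counted (the usual QUAST-style convention). N50 is the largest contig
#' length L such that contigs of length >= L sum to at least half of the
#' filtered assembly length; GC is computed over unambiguous bases only. An
#' assembly that is empty after filtering is not an error: it is reported with
#' `status = "no_assembly"` so batch logic can record the sample as failed.
#'
#' @param contigs contig tibble (`id`, `seq`).
#' @param min_contig_len minimum contig length retained, in bp.
#' @return a one-row tibble: `n_contigs`, `total_length`, `n50`, `gc_percent`,
#'   `status` (`"ok"` or `"no_assembly"`).
#' @export
assembly_stats <- function(contigs, min_contig_len = 500L) {
  check_seq_tbl(contigs)
  lens <- nchar(contigs$seq)
  keep <- lens >= min_contig_len
  if (!any(keep)) {
    return(tibble::tibble(n_contigs = 0L, total_length = 0, n50 = NA_real_,
                          gc_percent = NA_real_, status = "no_assembly"))
  }
  lens <- lens[keep]
  gc <- cpp_gc_counts(contigs$seq[keep])
  sorted <- sort(lens, decreasing = TRUE)
  total <- sum(sorted)
  n50 <- sorted[which(cumsum(sorted) >= total / 2)[1]]
  tibble::tibble(
    n_contigs = sum(keep),
    total_length = total,
    n50 = as.numeric(n50),
    gc_percent = 100 * gc[[1]] / gc[[2]],
    status = "ok"
  )
}

#' MinHash sketch of a genome or assembly
#'
#' Bottom-`sketch_size` sketch over the distinct canonical k-mers of the
#' sequence set, hashed with a fixed 64-bit mixer (splitmix64 of the
#' 2-bit-packed canonical k-mer) so sketches are reproducible across runs and
#' platforms. Sequences of identical content (or reverse complements) yield
#' identical sketches.
#'
#' @param seqs contig tibble (`id`, `seq`) or character vector of sequences.
#' @param k k-mer size.
#' @param sketch_size number of retained hash values.
#' @return a `genome_sketch` object.
#' @export
sketch_genome <- function(seqs, k = 21L, sketch_size = 1000L) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  hashes <- cpp_sketch(seqs, as.integer(k), as.integer(sketch_size))
  if (length(hashes) == 0) {
    warning("no k-mers of size ", k, ": empty sketch", call. = FALSE)
  }
  structure(list(k = as.integer(k), sketch_size = as.integer(sketch_size),
                 hashes = hashes),
            class = "genome_sketch")
}

#' @export
print.genome_sketch <- function(x, ...) {
  cat(sprintf("<genome_sketch> k=%d, %d/%d hashes\n",
              x$k, length(x$hashes), x$sketch_size))
  invisible(x)
}

#' Sketch Jaccard index and mash distance
#'
#' The Jaccard index is estimated on the merged bottom-s sketch of the two
#' inputs, and converted to a mash distance `d = -log(2j / (1 + j)) / k`.
#' Disjoint sketches (`j = 0`) are reported at the maximum distance 1.
#'
#' @param a,b `genome_sketch` objects with equal `k` and `sketch_size`.
#' @return a single numeric value.
#' @export
sketch_jaccard <- function(a, b) {
  stopifnot(inherits(a, "genome_sketch"), inherits(b, "genome_sketch"),
            a$k == b$k, a$sketch_size == b$sketch_size)
  merged <- sort(unique(c(a$hashes, b$hashes)))
  m <- head(merged, a$sketch_size)
  if (length(m) == 0) return(0)
  sum(m %in% a$hashes & m %in% b$hashes) / length(m)
}

#' @rdname sketch_jaccard
#' @export
mash_distance <- function(a, b) {
  j <- sketch_jaccard(a, b)
  if (j <= 0) return(1)
  min(1, -log(2 * j / (1 + j)) / a$k)
}

#' Select the closest reference genome by mash distance
#'
#' @param assembly_sketch `genome_sketch` of the query assembly.
#' @param reference_sketches named list of `genome_sketch` objects.
#' @return a one-row tibble: `label`, `mash_distance`. Ties are broken by
#'   lexicographic label.
#' @export
select_reference <- function(assembly_sketch, reference_sketches) {
  if (length(assembly_sketch$hashes) == 0) {
    stop("empty assembly sketch", call. = FALSE)
  }
  if (length(reference_sketches) == 0) stop("no reference sketches", call. = FALSE)
  d <- vapply(reference_sketches, mash_distance, numeric(1), a = assembly_sketch)
  res <- tibble::tibble(label = names(reference_sketches), mash_distance = unname(d))
  dplyr::slice_head(dplyr::arrange(res, .data$mash_distance, .data$label), n = 1)
}

#' Anchor contigs onto a reference genome
#'
#' Exact unique-k-mer anchoring (no gapped alignment): maximal runs of contig
#' k-mers matching reference-unique k-mers at consecutive positions are merged
#' into blocks of at least `min_block` bp, reported in 0-based half-open
#' reference coordinates. A deliberate simplification of a genome aligner,
#' adequate for low-divergence draft assemblies. Multiple reference replicons
#' are concatenated (with an N spacer) before anchoring.
#'
#' @param contigs contig tibble (`id`, `seq`).
#' @param reference reference sequence: a string, character vector of
#'   replicons, or a contig tibble.
#' @param k anchor k-mer size.
#' @param min_block minimum reported block length, in bp.
#' @return a `ref_alignment` object: block table, per-base coverage
#'   multiplicity over the reference, total aligned bases and reference length.
#' @export
map_contigs <- function(contigs, reference, k = 31L, min_block = 200L) {
  check_seq_tbl(contigs)
  if (is.data.frame(reference)) reference <- reference$seq
  ref <- paste(reference, collapse = strrep("N", k))
  blocks <- tibble::as_tibble(cpp_anchor_map(contigs$seq, ref, as.integer(k),
                                             as.integer(min_block)))
  blocks$contig <- contigs$id[blocks$contig]
  ref_length <- nchar(ref)
  covered <- integer(ref_length)
  if (nrow(blocks)) {
    delta <- integer(ref_length + 1L)
    for (i in seq_len(nrow(blocks))) {
      delta[blocks$ref_start[i] + 1L] <- delta[blocks$ref_start[i] + 1L] + 1L
      delta[blocks$ref_end[i] + 1L] <- delta[blocks$ref_end[i] + 1L] - 1L
    }
    covered <- cumsum(delta[seq_len(ref_length)])
  }
  structure(list(blocks = blocks, covered = covered,
                 aligned_bases = sum(blocks$ref_end - blocks$ref_start),
                 ref_length = ref_length),
            class = "ref_alignment")
}

#' @export
print.ref_alignment <- function(x, ...) {
  cat(sprintf("<ref_alignment> %d blocks, %.0f aligned bases on %d bp reference\n",
              nrow(x$blocks), x$aligned_bases, x$ref_length))
  invisible(x)
}

#' Duplication ratio and genome fraction of an anchored assembly
#'
#' The duplication ratio is the total aligned assembly bases divided by the
#' number of reference bases covered at least once; values above 1 indicate
#' redundant (possibly mixed) assembly content. The genome fraction is the
#' proportion of the reference covered at least once.
#'
#' @param aln a `ref_alignment` from [map_contigs()].
#' @return `duplication_ratio()`: a single numeric (>= 1 whenever any base is
#'   aligned), or `NA` when nothing aligns (not assessed).
#' @export
duplication_ratio <- function(aln) {
  stopifnot(inherits(aln, "ref_alignment"))
  covered1 <- sum(aln$covered >= 1L)
  if (covered1 == 0) return(NA_real_)
  aln$aligned_bases / covered1
}

#' @rdname duplication_ratio
#' @param ref_length optional reference length override (defaults to the
#'   alignment's own).
#' @export
genome_fraction <- function(aln, ref_length = aln$ref_length) {
  stopifnot(inherits(aln, "ref_alignment"))
  sum(aln$covered >= 1L) / ref_length
}
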