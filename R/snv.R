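# Read-level intragenus contamination detection via contaminating SNVs in
# core genes: bait reads to loci, pile up bases, count mixed sites, call.

#' Bait reads to core-gene loci
#'
#' Each read is assigned to the locus with which it shares the most canonical
#' k-mers (at least one; k-mers occurring in several loci are ignored).
#' Unassigned reads are dropped.
#'
#' @param reads read tibble (`id`, `seq`, optionally `qual`).
#' @param scheme a core `scheme`; the representative (first) allele of each
#'   locus is the bait.
#' @param k bait k-mer size.
#' @return the input rows that were baited, with a `locus` column.
#' @export
bait_reads <- function(reads, scheme, k = 31L) {
  check_seq_tbl(reads)
  stopifnot(inherits(scheme, "scheme"))
  baits <- vapply(scheme$alleles, function(a) a[[1]], character(1))
  hit <- cpp_bait(reads$seq, unname(baits), as.integer(k))
  out <- reads[hit > 0L, , drop = FALSE]
  out$locus <- scheme$loci[hit[hit > 0L]]
  tibble::as_tibble(out)
}

#' Pile up baited reads on their loci
#'
#' Reads are placed ungapped at the offset (and strand) supported by the most
#' exact k-mer anchors on the locus' representative allele; reads without an
#' anchor are dropped, as are bases below `min_base_qual` (indel-bearing reads
#' lose their anchors, a documented limitation of ungapped placement). Returns
#' per-site base counts for every site with non-zero filtered depth.
#'
#' @param baited output of [bait_reads()].
#' @param scheme the same core `scheme`.
#' @param k anchor k-mer size.
#' @param min_base_qual minimum Phred base quality for a base to enter the
#'   pileup (ignored when reads carry no qualities).
#' @return a tibble: `locus`, `pos` (0-based), `depth`, `A`, `C`, `G`, `T`.
#' @export
pileup <- function(baited, scheme, k = 31L, min_base_qual = 20L) {
  stopifnot(inherits(scheme, "scheme"))
  if (nrow(baited) == 0) {
    return(tibble::tibble(locus = character(), pos = integer(), depth = integer(),
                          A = integer(), C = integer(), G = integer(), T = integer()))
  }
  check_seq_tbl(baited)
  stopifnot("locus" %in% names(baited))
  have_qual <- "qual" %in% names(baited) && !anyNA(baited$qual)
  purrr::map_dfr(split(baited, baited$locus), function(grp) {
    locus <- grp$locus[1]
    ref <- scheme$alleles[[locus]][[1]]
    m <- cpp_pileup(grp$seq,
                    if (have_qual) grp$qual else character(0),
                    ref, as.integer(k), as.integer(min_base_qual))
    depth <- colSums(m)
    keep <- which(depth > 0)
    tibble::tibble(locus = locus, pos = keep - 1L, depth = depth[keep],
                   A = m[1, keep], C = m[2, keep], G = m[3, keep], T = m[4, keep])
  })
}

#' Contaminating SNV sites in a pileup
#'
#' A site is a contaminating SNV when its filtered depth reaches `min_depth`
#' and at least two distinct bases are each supported by `min_minor_reads`
#' reads, with the minor (second most frequent) base reaching
#' `min_minor_fraction` of the depth. Such sites indicate mixed input: a pure
#' isolate cannot carry two well-supported bases at one core-gene position.
#'
#' @param pileups tibble from [pileup()].
#' @param min_depth minimum site depth.
#' @param min_minor_reads minimum reads supporting each of the two bases.
#' @param min_minor_fraction minimum minor-base fraction of the site depth.
#' @return a list: `n_snvs`, `sites` (tibble with `minor_fraction`),
#'   `multiallelic_loci` (loci carrying two or more SNV sites).
#' @export
contaminating_snvs <- function(pileups, min_depth = 10L, min_minor_reads = 2L,
                               min_minor_fraction = 0.05) {
  if (nrow(pileups) == 0) {
    return(list(n_snvs = 0L, sites = pileups, multiallelic_loci = 0L))
  }
  # second-largest of the four base counts, vectorised via a sorting network
  hi1 <- pmax(pileups$A, pileups$C); lo1 <- pmin(pileups$A, pileups$C)
  hi2 <- pmax(pileups$G, pileups$T); lo2 <- pmin(pileups$G, pileups$T)
  second <- pmax(pmin(hi1, hi2), pmax(lo1, lo2))
  is_snv <- pileups$depth >= min_depth &
    second >= min_minor_reads &
    second / pileups$depth >= min_minor_fraction
  sites <- pileups[is_snv, , drop = FALSE]
  sites$minor_fraction <- second[is_snv] / sites$depth
  list(n_snvs = nrow(sites), sites = sites,
       multiallelic_loci = sum(table(sites$locus) >= 2L))
}

#' Contamination call from SNV evidence
#'
#' A sample is called contaminated when the contaminating-SNV count reaches
#' `snv_cutoff` or when any locus is multiallelic (two or more SNV sites on
#' one gene, the footprint of a second allele). The contaminant fraction is
#' estimated as the median minor-base fraction over SNV sites, in percent
#' (`NA`/not assessed when there are no SNV sites).
#'
#' @param snvs result of [contaminating_snvs()].
#' @param snv_cutoff minimum SNV count for a contamination call.
#' @return a one-row tibble: `n_snvs`, `multiallelic_loci`, `contaminated`,
#'   `est_contamination_percent`.
#' @export
contamination_call <- function(snvs, snv_cutoff = 3L) {
  est <- if (snvs$n_snvs > 0) 100 * median(snvs$sites$minor_fraction) else NA_real_
  tibble::tibble(
    n_snvs = snvs$n_snvs,
    multiallelic_loci = snvs$multiallelic_loci,
    contaminated = snvs$n_snvs >= snv_cutoff || snvs$multiallelic_loci >= 1L,
    est_contamination_percent = est
  )
}

#' Full read-level contamination detection
#'
#' Convenience chain: [bait_reads()], [pileup()], [contaminating_snvs()],
#' [contamination_call()].
#'
#' @inheritParams bait_reads
#' @inheritParams pileup
#' @inheritParams contaminating_snvs
#' @inheritParams contamination_call
#' @param bait_k bait k-mer size.
#' @return as [contamination_call()].
#' @export
detect_contamination <- function(reads, scheme, bait_k = 31L, k = 31L,
                                 min_base_qual = 20L, min_depth = 10L,
                                 min_minor_reads = 2L, min_minor_fraction = 0.05,
                                 snv_cutoff = 3L) {
  baited <- bait_reads(reads, scheme, bait_k)
  piles <- pileup(baited, scheme, k, min_base_qual)
  snvs <- contaminating_snvs(piles, min_depth, min_minor_reads, min_minor_fraction)
  contamination_call(snvs, snv_cutoff)
}
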