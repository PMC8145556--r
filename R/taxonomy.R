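# K-mer LCA classifier: read-level and contig-level majority-taxon fractions
# at species and genus rank.

#' Build a k-mer LCA index from labelled genomes
#'
#' Every canonical k-mer of the input genomes is assigned to the lowest common
#' ancestor of the taxa it occurs in: k-mers private to one species map to that
#' species, k-mers shared between species of one genus map to the genus, and
#' k-mers shared across genera are uninformative and dropped. The index is
#' deterministic for a fixed genome set.
#'
#' @param genomes tibble with columns `label` and `seq`; multiple rows per
#'   label are allowed (e.g. chromosome plus plasmids, or draft contigs).
#' @param taxonomy tibble with columns `label`, `species`, `genus` covering
#'   every genome label.
#' @param k k-mer size (at most 26 so packed k-mers stay exact in doubles).
#' @return a `kmer_index` object.
#' @export
build_kmer_index <- function(genomes, taxonomy, k = 21L) {
  stopifnot(all(c("label", "seq") %in% names(genomes)),
            all(c("label", "species", "genus") %in% names(taxonomy)))
  if (k > 26L) stop("k must be <= 26", call. = FALSE)
  unknown <- setdiff(genomes$label, taxonomy$label)
  if (length(unknown)) {
    stop("genome label(s) missing from taxonomy: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  taxonomy <- dplyr::distinct(taxonomy, .data$label, .data$species, .data$genus)
  species <- sort(unique(taxonomy$species))
  genus <- sort(unique(taxonomy$genus))
  sp_genus <- vapply(species, function(s) {
    unique(taxonomy$genus[taxonomy$species == s])[1]
  }, character(1))
  genus_of_species <- match(sp_genus, genus) - 1L
  sp_of_label <- stats::setNames(match(taxonomy$species, species) - 1L, taxonomy$label)
  idx <- cpp_build_index(genomes$seq, unname(sp_of_label[genomes$label]),
                         genus_of_species, as.integer(k))
  structure(list(k = as.integer(k), key = idx$key, node = idx$node,
                 species = species, genus = genus,
                 genus_of_species = genus_of_species),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %d informative k-mers, %d species / %d genera\n",
              x$k, length(x$key), length(x$species), length(x$genus)))
  invisible(x)
}

#' Classify sequence units against a k-mer index
#'
#' Each unit (read or contig) is assigned the species with the most k-mer
#' hits; k-mers resolved only at genus level vote at genus rank. Ties between
#' species collapse to their common ancestor, and units without informative
#' hits are unclassified (`NA`).
#'
#' @param units tibble with columns `id` and `seq`.
#' @param index a `kmer_index`.
#' @return a tibble: `id`, `species`, `genus`, `n_hits`.
#' @export
classify_units <- function(units, index) {
  check_seq_tbl(units)
  stopifnot(inherits(index, "kmer_index"))
  m <- cpp_classify(units$seq, index$key, index$node, index$genus_of_species,
                    length(index$genus), index$k)
  tibble::tibble(
    id = units$id,
    species = ifelse(m[, 1] >= 0, index$species[m[, 1] + 1L], NA_character_),
    genus = ifelse(m[, 2] >= 0, index$genus[m[, 2] + 1L], NA_character_),
    n_hits = m[, 3]
  )
}

majority_fraction_impl <- function(cls, rank, weights) {
  taxon <- if (rank == "species") cls$species else cls$genus
  classified <- !is.na(taxon)
  total_w <- sum(weights)
  if (!any(classified)) {
    return(tibble::tibble(rank = rank, majority_taxon = NA_character_,
                          fraction = NA_real_, unclassified_fraction = 1,
                          n_units = nrow(cls), status = "not-assessed"))
  }
  tab <- tapply(weights[classified], taxon[classified], sum)
  best <- which.max(tab)
  tibble::tibble(
    rank = rank,
    majority_taxon = names(tab)[best],
    fraction = unname(tab[best]) / sum(tab),
    unclassified_fraction = 1 - sum(tab) / total_w,
    n_units = nrow(cls),
    status = "ok"
  )
}

#' Majority-taxon fraction of a read set or assembly
#'
#' `majority_fraction_reads()` classifies each read (unit weight 1);
#' `majority_fraction_contigs()` classifies each contig by its best hit and
#' weights it by contig length, so a multi-copy plasmid contributes once
#' regardless of its read depth. Fractions are computed over classified units
#' only; the unclassified share is reported separately. The read-level
#' fraction estimates intergenus contamination; the contig-level fraction
#' corrects the multi-copy plasmid bias of read counting.
#'
#' @param reads,contigs sequence tibbles (`id`, `seq`).
#' @param index a `kmer_index`.
#' @param rank `"species"` or `"genus"`.
#' @return a one-row tibble: `rank`, `majority_taxon`, `fraction`,
#'   `unclassified_fraction`, `n_units`, `status`.
#' @export
majority_fraction_reads <- function(reads, index, rank = c("species", "genus")) {
  rank <- match.arg(rank)
  cls <- classify_units(reads, index)
  majority_fraction_impl(cls, rank, rep(1, nrow(cls)))
}

#' @rdname majority_fraction_reads
#' @export
majority_fraction_contigs <- function(contigs, index, rank = c("species", "genus")) {
  rank <- match.arg(rank)
  cls <- classify_units(contigs, index)
  majority_fraction_impl(cls, rank, nchar(contigs$seq))
}
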