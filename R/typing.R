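# MLST and core-genome (cgMLST-like) typing: allele calling, sequence types,
# duplicated-allele contamination signal, scheme construction, allele
# distances, relatedness categories and core-gene completeness/duplication.

#' Construct a typing scheme
#'
#' A scheme holds, per locus, the known allele sequences under ids
#' `<locus>_<n>`, optionally with a profile table mapping sequence types (ST)
#' to allele numbers (classical 7-gene MLST).
#'
#' @param alleles named list: locus -> named character vector of allele
#'   sequences, names formatted `<locus>_<n>`.
#' @param profiles optional tibble with column `ST` and one column per locus
#'   holding allele numbers.
#' @param kind `"mlst"` or `"core"`.
#' @return a `scheme` object.
#' @export
new_scheme <- function(alleles, profiles = NULL, kind = c("core", "mlst")) {
  kind <- match.arg(kind)
  stopifnot(is.list(alleles), length(alleles) > 0)
  for (locus in names(alleles)) {
    a <- alleles[[locus]]
    if (anyDuplicated(a)) {
      stop("duplicate allele sequences within locus ", locus, call. = FALSE)
    }
    if (is.null(names(a)) || !all(startsWith(names(a), paste0(locus, "_")))) {
      stop("allele ids of locus ", locus, " must be '", locus, "_<n>'", call. = FALSE)
    }
  }
  if (!is.null(profiles)) {
    stopifnot("ST" %in% names(profiles),
              all(names(alleles) %in% names(profiles)))
    for (locus in names(alleles)) {
      known <- as.integer(sub(".*_", "", names(alleles[[locus]])))
      bad <- setdiff(profiles[[locus]], known)
      if (length(bad)) {
        stop("profile references unknown allele(s) of ", locus, ": ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  structure(list(kind = kind, loci = names(alleles), alleles = alleles,
                 profiles = profiles),
            class = "scheme")
}

#' @export
print.scheme <- function(x, ...) {
  cat(sprintf("<scheme:%s> %d loci, %d alleles%s\n", x$kind, length(x$loci),
              sum(lengths(x$alleles)),
              if (is.null(x$profiles)) "" else sprintf(", %d ST profiles", nrow(x$profiles))))
  invisible(x)
}

#' Read or write a scheme directory
#'
#' The on-disk format is one FASTA per locus (`<locus>.fasta`, allele ids
#' `<locus>_<n>`) plus an optional PubMLST-style `profiles.tsv` with header
#' `ST<TAB>locus1...locusN`.
#'
#' @param dir scheme directory.
#' @param kind `"core"` or `"mlst"`.
#' @return `read_scheme()` returns a `scheme`; `write_scheme()` returns `dir`
#'   invisibly.
#' @export
read_scheme <- function(dir, kind = c("core", "mlst")) {
  kind <- match.arg(kind)
  fastas <- sort(list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE))
  if (!length(fastas)) stop("no locus FASTA files in ", dir, call. = FALSE)
  alleles <- lapply(fastas, function(f) {
    tbl <- read_sequences(f, "fasta")
    stats::setNames(tbl$seq, tbl$id)
  })
  names(alleles) <- sub("\\.(fa|fasta)$", "", basename(fastas))
  prof_path <- file.path(dir, "profiles.tsv")
  profiles <- NULL
  if (file.exists(prof_path)) {
    profiles <- readr::read_tsv(prof_path, col_types = readr::cols())
  }
  new_scheme(alleles, profiles, kind)
}

#' @rdname read_scheme
#' @param scheme a `scheme` object.
#' @export
write_scheme <- function(scheme, dir) {
  stopifnot(inherits(scheme, "scheme"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (locus in scheme$loci) {
    a <- scheme$alleles[[locus]]
    write_fasta(tibble::tibble(id = names(a), seq = unname(a)),
                file.path(dir, paste0(locus, ".fasta")))
  }
  if (!is.null(scheme$profiles)) {
    readr::write_tsv(scheme$profiles, file.path(dir, "profiles.tsv"))
  }
  invisible(dir)
}

#' Call scheme alleles in an assembly
#'
#' Each known allele is searched as an exact full-length substring of the
#' contigs, on both strands; all matching alleles are recorded per locus, so a
#' mixed assembly can yield several alleles at one locus.
#'
#' @param contigs contig tibble (`id`, `seq`).
#' @param scheme a `scheme`.
#' @return an `allele_calls` tibble: `locus`, `alleles` (list column of
#'   matched allele ids), `n_alleles`.
#' @export
call_alleles <- function(contigs, scheme) {
  check_seq_tbl(contigs)
  stopifnot(inherits(scheme, "scheme"))
  hay <- contigs$seq
  calls <- purrr::map(scheme$loci, function(locus) {
    a <- scheme$alleles[[locus]]
    hit <- vapply(seq_along(a), function(i) {
      any(stringi::stri_detect_fixed(hay, a[[i]])) ||
        any(stringi::stri_detect_fixed(hay, revcomp(a[[i]])))
    }, logical(1))
    names(a)[hit]
  })
  tibble::tibble(locus = scheme$loci, alleles = calls,
                 n_alleles = lengths(calls))
}

#' Allele profile from calls
#'
#' @param calls an `allele_calls` tibble.
#' @return named character vector locus -> allele id, `NA` where a locus has
#'   zero or more than one call.
#' @export
allele_profile <- function(calls) {
  stats::setNames(
    vapply(calls$alleles, function(a) if (length(a) == 1) a else NA_character_,
           character(1)),
    calls$locus)
}

#' Sequence type of an assembly
#'
#' An ST is returned only when every scheme locus has exactly one called
#' allele and the resulting allele-number tuple matches a profile row.
#'
#' @param calls an `allele_calls` tibble.
#' @param scheme a `scheme` with a profile table.
#' @return the ST (as stored in the profile table) or `"unknown"`.
#' @export
sequence_type <- function(calls, scheme) {
  stopifnot(inherits(scheme, "scheme"))
  if (is.null(scheme$profiles)) stop("scheme has no ST profiles", call. = FALSE)
  prof <- allele_profile(calls)
  if (anyNA(prof)) return("unknown")
  nums <- as.integer(sub(".*_", "", prof))
  tab <- scheme$profiles
  hit <- rep(TRUE, nrow(tab))
  for (i in seq_along(scheme$loci)) {
    hit <- hit & tab[[scheme$loci[i]]] == nums[i]
  }
  if (!any(hit)) return("unknown")
  as.character(tab$ST[which(hit)[1]])
}

#' Duplicated-allele contamination signal
#'
#' Counts loci carrying two or more distinct alleles; a sample is considered
#' contaminated by this signal when at least one locus is duplicated. A
#' contaminant sharing the subject's sequence type carries identical alleles
#' and is invisible to this check.
#'
#' @param calls an `allele_calls` tibble.
#' @return a one-row tibble: `duplicated_loci`, `contaminated`.
#' @export
duplicated_alleles <- function(calls) {
  n <- sum(calls$n_alleles >= 2L)
  tibble::tibble(duplicated_loci = n, contaminated = n >= 1L)
}

#' Build a core-gene scheme from reference genes and genomes
#'
#' Alignment-free scheme construction: each reference gene is located in each
#' genome by exact-k-mer anchored ungapped placement and kept as a scheme
#' locus only when it is found exactly once, at full length and at least
#' `min_identity` sequence identity, in at least `min_presence` of the
#' genomes, and found in duplicate in at most `1 - min_presence` of them
#' (single-copy requirement). Distinct observed sequences become numbered
#' alleles in order of first observation.
#'
#' @param ref_genes tibble (`id`, `seq`) of reference gene sequences; `id`
#'   becomes the locus name.
#' @param genomes tibble (`label`, `seq`); rows sharing a label are treated as
#'   one (draft) genome.
#' @param min_presence minimum fraction of genomes containing the locus.
#' @param min_identity minimum ungapped identity of a placement.
#' @param k anchor k-mer size.
#' @return a `scheme` of kind `"core"`.
#' @export
build_core_scheme <- function(ref_genes, genomes, min_presence = 0.95,
                              min_identity = 0.90, k = 31L) {
  check_seq_tbl(ref_genes)
  stopifnot(all(c("label", "seq") %in% names(genomes)))
  labels <- unique(genomes$label)
  if (length(labels) < 2) stop("need at least 2 genomes", call. = FALSE)
  spacer <- strrep("N", k)
  subj <- vapply(labels, function(l) {
    paste(genomes$seq[genomes$label == l], collapse = spacer)
  }, character(1))
  n_loci <- nrow(ref_genes)
  present_once <- integer(n_loci)
  duplicated_in <- integer(n_loci)
  observed <- vector("list", n_loci) # per locus: character vector of allele seqs
  for (g in seq_along(subj)) {
    loc <- cpp_locate(ref_genes$seq, subj[[g]], as.integer(k), 2L)
    loc <- loc[loc$identity >= min_identity, , drop = FALSE]
    counts <- tabulate(loc$query, nbins = n_loci)
    present_once <- present_once + (counts == 1L)
    duplicated_in <- duplicated_in + (counts >= 2L)
    single <- loc[loc$query %in% which(counts == 1L), , drop = FALSE]
    for (r in seq_len(nrow(single))) {
      q <- single$query[r]
      s <- substr(subj[[g]], single$offset[r] + 1L,
                  single$offset[r] + nchar(ref_genes$seq[q]))
      if (single$strand[r] < 0) s <- revcomp(s)
      if (!s %in% observed[[q]]) observed[[q]] <- c(observed[[q]], s)
    }
  }
  n_gen <- length(subj)
  keep <- present_once >= min_presence * n_gen &
    duplicated_in <= (1 - min_presence) * n_gen
  if (!any(keep)) stop("no loci retained for the core scheme", call. = FALSE)
  alleles <- stats::setNames(lapply(which(keep), function(q) {
    a <- observed[[q]]
    stats::setNames(a, paste0(ref_genes$id[q], "_", seq_along(a)))
  }), ref_genes$id[keep])
  new_scheme(alleles, NULL, "core")
}

#' Allele distance between two profiles
#'
#' Hamming distance over the loci that are non-missing in both profiles
#' (missing loci are ignored); comparing profiles without any shared assessed
#' locus is an error.
#'
#' @param a,b named character vectors locus -> allele id (`NA` = missing), as
#'   returned by [allele_profile()], over the same scheme.
#' @return integer allele distance.
#' @export
allele_distance <- function(a, b) {
  loci <- intersect(names(a), names(b))
  if (!length(loci)) stop("profiles share no loci", call. = FALSE)
  ok <- !is.na(a[loci]) & !is.na(b[loci])
  if (!any(ok)) stop("no comparable (non-missing) loci", call. = FALSE)
  sum(a[loci][ok] != b[loci][ok])
}

#' Relatedness category of a contaminant
#'
#' Categories follow the allele-distance bins used for contamination study
#' design: close (same ST, 0 allele distance), intermediate (allele distance
#' 1-6) and distant (allele distance >= 7). An allele distance of 1 with a
#' different ST falls in no published bin and is assigned to the nearest,
#' intermediate.
#'
#' @param same_st do the two samples share a sequence type?
#' @param ad allele distance (>= 0).
#' @return `"close"`, `"intermediate"` or `"distant"`.
#' @export
categorize_relatedness <- function(same_st, ad) {
  stopifnot(ad >= 0)
  if (ad >= 7) return("distant")
  if (same_st && ad == 0) return("close")
  "intermediate"
}

#' Core-gene completeness and duplication assessment
#'
#' For each scheme locus the representative allele is located in the assembly
#' (exact-k-mer anchored, ungapped, both strands, identity >= `min_identity`).
#' A locus is unique when placed exactly once and no second distinct allele
#' matches exactly; it is duplicated when placed two or more times or when two
#' or more distinct alleles match. Mirroring single-copy-orthologue practice,
#' a contamination warning is raised only when more than one locus is
#' duplicated.
#'
#' @param contigs contig tibble (`id`, `seq`).
#' @param scheme a core `scheme`.
#' @param min_identity minimum placement identity.
#' @param k anchor k-mer size.
#' @return a one-row tibble: `n_loci`, `unique_fraction` (percent),
#'   `duplicated_count`, `contamination_warning`.
#' @export
core_gene_assessment <- function(contigs, scheme, min_identity = 0.90, k = 31L) {
  check_seq_tbl(contigs)
  stopifnot(inherits(scheme, "scheme"))
  spacer <- strrep("N", k)
  subject <- paste(contigs$seq, collapse = spacer)
  reps <- vapply(scheme$alleles, function(a) a[[1]], character(1))
  loc <- cpp_locate(unname(reps), subject, as.integer(k), 2L)
  loc <- loc[loc$identity >= min_identity, , drop = FALSE]
  placements <- tabulate(loc$query, nbins = length(reps))
  multi_allele <- vapply(scheme$loci, function(locus) {
    a <- scheme$alleles[[locus]]
    if (length(a) < 2) return(FALSE)
    hits <- vapply(a, function(s) {
      stringi::stri_detect_fixed(subject, s) ||
        stringi::stri_detect_fixed(subject, revcomp(s))
    }, logical(1))
    sum(hits) >= 2
  }, logical(1))
  dup <- placements >= 2L | multi_allele
  uniq <- placements == 1L & !dup
  tibble::tibble(
    n_loci = length(reps),
    unique_fraction = 100 * sum(uniq) / length(reps),
    duplicated_count = sum(dup),
    contamination_warning = sum(dup) > 1L
  )
}
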