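# Synthetic-data generator: genomes with designated core genes, isolate-level
# accessory variation, relatives at a controlled allele distance, plasmids,
# substitution-error reads, read mixtures and truth-aware pseudo-assemblies.

random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Simulate a bacterial genome with designated core genes
#'
#' Bases are i.i.d. at the GC target. `n_core_genes` non-overlapping gene
#' intervals of `gene_len` bp are laid out with even intergenic spacing, and
#' one accessory segment of `accessory_len` bp is placed after the last gene
#' — the region that [simulate_isolate()] resamples to emulate isolate-level
#' gene-content variation. Deterministic for a fixed seed.
#'
#' @param species,genus taxon labels.
#' @param length genome length, bp.
#' @param gc GC target as a proportion.
#' @param n_core_genes,gene_len core-gene layout.
#' @param accessory_len accessory segment length, bp.
#' @param seed RNG seed (`NULL` uses the current RNG state).
#' @return a `synthetic_taxon` object.
#' @export
simulate_genome <- function(species, genus, length = 200000L, gc = 0.5,
                            n_core_genes = 100L, gene_len = 1000L,
                            accessory_len = 8000L, seed = NULL) {
  need <- n_core_genes * gene_len + accessory_len
  if (length < need + n_core_genes + 2L) {
    stop("genome too short for the requested gene layout", call. = FALSE)
  }
  with_seed_if(seed, {
    gap <- (length - need) %/% (n_core_genes + 2L)
    starts <- gap + (seq_len(n_core_genes) - 1L) * (gene_len + gap)
    genes <- tibble::tibble(
      locus = sprintf("locus_%03d", seq_len(n_core_genes)),
      start = starts, end = starts + gene_len)
    acc_start <- max(genes$end) + gap
    stopifnot(acc_start + accessory_len <= length)
    structure(list(species = species, genus = genus,
                   seq = random_dna(length, gc), gc_target = gc,
                   genes = genes,
                   accessory = list(start = acc_start, len = accessory_len),
                   plasmids = tibble::tibble(label = character(),
                                             seq = character(),
                                             copy_number = integer())),
              class = "synthetic_taxon")
  })
}

#' @export
print.synthetic_taxon <- function(x, ...) {
  cat(sprintf("<synthetic_taxon> %s (%s): %d bp, %d core genes, %d plasmid(s)\n",
              x$species, x$genus, nchar(x$seq), nrow(x$genes), nrow(x$plasmids)))
  invisible(x)
}

#' Core-gene sequences of a synthetic taxon
#'
#' @param taxon a `synthetic_taxon`.
#' @return tibble (`id`, `seq`), one row per core gene.
#' @export
gene_seqs <- function(taxon) {
  stopifnot(inherits(taxon, "synthetic_taxon"))
  tibble::tibble(id = taxon$genes$locus,
                 seq = substring(taxon$seq, taxon$genes$start + 1L,
                                 taxon$genes$end))
}

#' Attach a plasmid to a synthetic taxon
#'
#' The plasmid is sampled by the read simulator at `copy_number` times the
#' chromosomal rate and emitted once by the pseudo-assembler. `label` is the
#' taxon name the plasmid is indexed under, allowing discordantly labelled
#' high-copy plasmids (the classification-bias scenario).
#'
#' @param taxon a `synthetic_taxon`.
#' @param length plasmid length, bp.
#' @param copy_number plasmid copies per chromosome.
#' @param label taxon label used when the plasmid enters a k-mer index.
#' @param gc plasmid GC target.
#' @param seed RNG seed.
#' @return the modified `synthetic_taxon`.
#' @export
add_plasmid <- function(taxon, length = 5000L, copy_number = 10L,
                        label = taxon$species, gc = taxon$gc_target, seed = NULL) {
  stopifnot(inherits(taxon, "synthetic_taxon"))
  taxon$plasmids <- dplyr::bind_rows(
    taxon$plasmids,
    tibble::tibble(label = label,
                   seq = with_seed_if(seed, random_dna(length, gc)),
                   copy_number = as.integer(copy_number)))
  taxon
}

#' Simulate an isolate of a species
#'
#' Produces a same-species isolate by resampling the accessory segment with a
#' new length (log-normal) and GC (normal around the species target). Core
#' genes are untouched, so typing results are unchanged; assembly length and
#' GC vary the way accessory gene content makes them vary between real
#' isolates of one species. Used to build the pure populations from which
#' species thresholds are derived.
#'
#' @param taxon a `synthetic_taxon` (the species base genome).
#' @param meanlog,sdlog accessory length distribution (log scale, bp).
#' @param gc_sd standard deviation of the accessory GC around the species
#'   target.
#' @param seed RNG seed.
#' @return a new `synthetic_taxon` of the same species.
#' @export
simulate_isolate <- function(taxon, meanlog = log(8000), sdlog = 0.5,
                             gc_sd = 0.05, seed = NULL) {
  stopifnot(inherits(taxon, "synthetic_taxon"))
  with_seed_if(seed, {
    len <- max(500L, round(rlnorm(1, meanlog, sdlog)))
    gc <- min(0.8, max(0.2, rnorm(1, taxon$gc_target, gc_sd)))
    acc <- taxon$accessory
    pre <- substr(taxon$seq, 1L, acc$start)
    post <- substr(taxon$seq, acc$start + acc$len + 1L, nchar(taxon$seq))
    taxon$seq <- paste0(pre, random_dna(len, gc), post)
    taxon$accessory$len <- len
    taxon
  })
}

#' Simulate a relative at a target allele distance
#'
#' Exactly `target_ad` randomly chosen core genes receive
#' `subs_per_allele` substitutions each (changing their allele); all other
#' positions are untouched, so the measured allele distance to the source
#' genome equals `target_ad` and the relative carries the same species and
#' genus labels. `target_ad = 0` returns an identical genome (a same-ST
#' "close" relative).
#'
#' @param taxon a `synthetic_taxon`.
#' @param target_ad number of core genes to mutate.
#' @param subs_per_allele substitutions per changed gene.
#' @param seed RNG seed.
#' @return a `synthetic_taxon` with a `changed_loci` element.
#' @export
simulate_relative <- function(taxon, target_ad, subs_per_allele = 3L, seed = NULL) {
  stopifnot(inherits(taxon, "synthetic_taxon"),
            target_ad <= nrow(taxon$genes))
  with_seed_if(seed, {
    picked <- sort(sample(nrow(taxon$genes), target_ad))
    s <- strsplit(taxon$seq, "", fixed = TRUE)[[1]]
    for (i in picked) {
      gene_start <- taxon$genes$start[i]
      gene_len <- taxon$genes$end[i] - gene_start
      pos <- gene_start + sample(gene_len, subs_per_allele)
      for (p in pos) {
        s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
      }
    }
    taxon$seq <- paste(s, collapse = "")
    taxon$changed_loci <- taxon$genes$locus[picked]
    taxon
  })
}

#' Simulate substitution-error short reads
#'
#' Uniform start positions and strands over the chromosome and plasmids
#' (plasmids weighted by copy number), so the chromosome is covered at
#' `coverage` and each plasmid at `copy_number * coverage`. Per-base
#' qualities are drawn from a two-point Q40/Q10 mixture whose implied mean
#' error equals `error_rate`, and substitution errors are generated
#' conditional on each base's quality, so qualities and errors agree. With
#' `error_rate = 0` reads are exact substrings at uniform Q40. Indels and
#' quality-by-cycle structure are not modelled.
#'
#' @param taxon a `synthetic_taxon`.
#' @param coverage target chromosomal depth.
#' @param read_len read length, bp.
#' @param error_rate mean per-base substitution rate in `[0, 0.05]`.
#' @param seed RNG seed.
#' @param id_prefix prefix for read ids.
#' @return a read tibble (`id`, `seq`, `qual`).
#' @export
simulate_reads <- function(taxon, coverage, read_len = 150L, error_rate = 0.01,
                           seed = NULL, id_prefix = "r") {
  stopifnot(inherits(taxon, "synthetic_taxon"), coverage > 0)
  if (error_rate < 0 || error_rate > 0.05) {
    stop("error_rate must be in [0, 0.05]", call. = FALSE)
  }
  seqs <- c(taxon$seq, taxon$plasmids$seq)
  weights <- c(nchar(taxon$seq),
               nchar(taxon$plasmids$seq) * taxon$plasmids$copy_number)
  n_reads <- max(1L, round(coverage * sum(weights) / read_len))
  q_hi <- 40L; q_lo <- 10L
  p_lo <- if (error_rate == 0) -1 else {
    (error_rate - 10^(-q_hi / 10)) / (10^(-q_lo / 10) - 10^(-q_hi / 10))
  }
  sim <- with_seed_if(seed, {
    cpp_simulate_reads(seqs, weights, n_reads, as.integer(read_len),
                       p_lo, q_hi, q_lo)
  })
  tibble::tibble(id = sprintf("%s%07d", id_prefix, seq_len(n_reads)),
                 seq = sim$seq, qual = sim$qual)
}

#' Mix subject and contaminant reads at a defined ratio
#'
#' The mixture holds `floor(r * total_reads)` contaminant reads and subject
#' reads for the remainder, subsampled without replacement and shuffled
#' deterministically per seed. An `origin` column records the ground truth.
#'
#' @param subject_reads,contaminant_reads read tibbles.
#' @param r contaminant proportion in `[0, 1)`.
#' @param total_reads mixture size (default: the subject pool size).
#' @param seed RNG seed.
#' @return a read tibble with an `origin` column.
#' @export
mix_reads <- function(subject_reads, contaminant_reads = NULL, r = 0,
                      total_reads = nrow(subject_reads), seed = NULL) {
  stopifnot(r >= 0, r < 1)
  n_c <- floor(r * total_reads)
  n_s <- total_reads - n_c
  if (n_s > nrow(subject_reads)) stop("not enough subject reads", call. = FALSE)
  if (n_c > 0 && (is.null(contaminant_reads) || n_c > nrow(contaminant_reads))) {
    stop("not enough contaminant reads", call. = FALSE)
  }
  with_seed_if(seed, {
    s <- subject_reads[sample(nrow(subject_reads), n_s), ]
    s$id <- paste0("s_", s$id)
    s$origin <- "subject"
    out <- s
    if (n_c > 0) {
      cont <- contaminant_reads[sample(nrow(contaminant_reads), n_c), ]
      cont$id <- paste0("c_", cont$id)
      cont$origin <- "contaminant"
      out <- dplyr::bind_rows(s, cont)
    }
    out[sample(nrow(out)), ]
  })
}

# Random fragmentation of one sequence into about `frag_n` pieces with
# log-normal sizes; the pieces tile the sequence exactly. Breakpoints falling
# inside a gene interval are snapped to the nearest gene boundary: at the
# coverage this simulator targets, real assemblies break in intergenic or
# repeat regions, not inside contiguous single-copy core genes.
fragment_seq <- function(seq, frag_n, genes = NULL, sdlog = 0.7, min_frags = 3L) {
  n <- max(min_frags, rpois(1, frag_n))
  L <- nchar(seq)
  w <- rlnorm(n, 0, sdlog)
  bounds <- round(cumsum(w) / sum(w) * L)
  if (!is.null(genes) && nrow(genes)) {
    snap <- function(b) {
      hit <- which(genes$start < b & b < genes$end)
      if (!length(hit)) return(b)
      if (b - genes$start[hit[1]] < genes$end[hit[1]] - b) {
        genes$start[hit[1]]
      } else {
        genes$end[hit[1]]
      }
    }
    bounds <- vapply(bounds, snap, numeric(1))
  }
  bounds <- unique(c(0L, sort(bounds), L))
  bounds <- bounds[bounds >= 0 & bounds <= L]
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  keep <- ends >= starts
  substring(seq, starts[keep], ends[keep])
}

#' Truth-aware pseudo-assembly of a (possibly mixed) sample
#'
#' A mechanistic stand-in for a de novo assembler. The subject genome is
#' emitted as roughly `frag_n` fragments with log-normal sizes that tile it
#' exactly, plus one contig per plasmid. Contaminant sequence enters the
#' assembly only when its effective depth `coverage * ratio` reaches
#' `min_assembly_depth`: a different-genus contaminant then contributes its
#' own fragments (separate contigs), while a same-genus contaminant — whose
#' backbone co-assembles with the subject — contributes only its divergent
#' core-gene copies as extra short contigs, which is what drives duplicated
#' alleles and duplicated core genes. Below that depth contaminant reads
#' leave no trace in the assembly.
#'
#' @param subject a `synthetic_taxon`.
#' @param contaminant a `synthetic_taxon` or `NULL` for a pure sample.
#' @param ratio contaminant read proportion.
#' @param coverage total sample depth.
#' @param min_assembly_depth minimum effective contaminant depth for
#'   contaminant sequence to assemble.
#' @param frag_n expected fragment count per genome.
#' @param seed RNG seed.
#' @return a contig tibble (`id`, `seq`).
#' @export
pseudo_assemble <- function(subject, contaminant = NULL, ratio = 0,
                            coverage = 50, min_assembly_depth = 10,
                            frag_n = 40L, seed = NULL) {
  stopifnot(inherits(subject, "synthetic_taxon"))
  with_seed_if(seed, {
    frags <- fragment_seq(subject$seq, frag_n, subject$genes)
    contigs <- tibble::tibble(
      id = sprintf("ctg_%03d", seq_along(frags)), seq = frags)
    if (nrow(subject$plasmids)) {
      contigs <- dplyr::bind_rows(contigs, tibble::tibble(
        id = sprintf("plasmid_%02d", seq_len(nrow(subject$plasmids))),
        seq = subject$plasmids$seq))
    }
    if (!is.null(contaminant) && coverage * ratio >= min_assembly_depth) {
      if (contaminant$genus != subject$genus) {
        cf <- fragment_seq(contaminant$seq, frag_n, contaminant$genes)
        extra <- tibble::tibble(id = sprintf("ctg_c_%03d", seq_along(cf)), seq = cf)
        if (nrow(contaminant$plasmids)) {
          extra <- dplyr::bind_rows(extra, tibble::tibble(
            id = sprintf("plasmid_c_%02d", seq_len(nrow(contaminant$plasmids))),
            seq = contaminant$plasmids$seq))
        }
        contigs <- dplyr::bind_rows(contigs, extra)
      } else {
        subj_genes <- gene_seqs(subject)
        cont_genes <- gene_seqs(contaminant)
        diverged <- which(subj_genes$seq != cont_genes$seq)
        if (length(diverged)) {
          contigs <- dplyr::bind_rows(contigs, tibble::tibble(
            id = sprintf("ctg_dup_%s", cont_genes$id[diverged]),
            seq = cont_genes$seq[diverged]))
        }
      }
    }
    contigs
  })
}
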