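# Contamination benchmark harness: a default synthetic panel, panel threshold
# derivation from pure isolate populations, the panel runner and the
# per-metric sensitivity/specificity table.

#' Default synthetic genus panel
#'
#' Four synthetic genera (one species each) with distinct GC targets spanning
#' the range typical of foodborne bacterial pathogens, 200 kb genomes with
#' 100 core genes of 1 kb. Genomes of different genera share no k-mers beyond
#' chance, so the panel separates intergenus from intragenus effects cleanly.
#'
#' @param seed RNG seed.
#' @param n_genera number of genera.
#' @param gc_targets per-genus GC targets.
#' @param genome_length,n_core_genes,gene_len genome layout, see
#'   [simulate_genome()].
#' @return named list of `synthetic_taxon` objects.
#' @export
panel_taxa <- function(seed = 1L, n_genera = 4L,
                       gc_targets = c(0.30, 0.40, 0.50, 0.60),
                       genome_length = 200000L, n_core_genes = 100L,
                       gene_len = 1000L) {
  stopifnot(n_genera <= length(LETTERS), length(gc_targets) >= n_genera)
  taxa <- lapply(seq_len(n_genera), function(i) {
    simulate_genome(species = sprintf("species%s", LETTERS[i]),
                    genus = sprintf("genus%s", LETTERS[i]),
                    length = genome_length, gc = gc_targets[i],
                    n_core_genes = n_core_genes, gene_len = gene_len,
                    seed = seed + i)
  })
  stats::setNames(taxa, vapply(taxa, `[[`, character(1), "species"))
}

#' Typing schemes for a panel subject and its relatives
#'
#' Builds the subject's core scheme (all core genes) and a 7-gene MLST scheme
#' with an ST profile table directly from the known gene coordinates: every
#' distinct gene sequence observed across the subject and its relatives
#' becomes a numbered allele, and each input genome's allele combination a
#' profile (STs numbered by first observation).
#'
#' @param subject a `synthetic_taxon`.
#' @param relatives list of `synthetic_taxon` relatives of the subject.
#' @param n_mlst number of leading loci forming the MLST scheme.
#' @return a list with elements `core` and `mlst` (both `scheme`s).
#' @export
panel_scheme <- function(subject, relatives = list(), n_mlst = 7L) {
  genomes <- c(list(subject), relatives)
  gene_tbl <- lapply(genomes, gene_seqs)
  loci <- gene_tbl[[1]]$id
  alleles <- stats::setNames(vector("list", length(loci)), loci)
  prof <- matrix(NA_integer_, nrow = length(genomes), ncol = length(loci))
  for (j in seq_along(loci)) {
    seqs_j <- vapply(gene_tbl, function(g) g$seq[j], character(1))
    uniq <- unique(seqs_j)
    alleles[[j]] <- stats::setNames(uniq, paste0(loci[j], "_", seq_along(uniq)))
    prof[, j] <- match(seqs_j, uniq)
  }
  core <- new_scheme(alleles, NULL, "core")
  mlst_loci <- loci[seq_len(n_mlst)]
  key <- apply(prof[, seq_len(n_mlst), drop = FALSE], 1, paste, collapse = "-")
  st <- match(key, unique(key))
  profiles <- tibble::as_tibble(as.data.frame(
    prof[!duplicated(key), seq_len(n_mlst), drop = FALSE]))
  names(profiles) <- mlst_loci
  profiles <- dplyr::bind_cols(tibble::tibble(ST = unique(st)), profiles)
  mlst <- new_scheme(alleles[mlst_loci], profiles, "mlst")
  list(core = core, mlst = mlst)
}

#' Derive panel QC thresholds from pure isolate populations
#'
#' For each species, `n_replicates` pure isolates (accessory-genome variants,
#' see [simulate_isolate()]) are pseudo-assembled and their assembly metrics
#' collected; species threshold ranges are the 5%/95% quantiles via
#' [derive_species_thresholds()]. N50 keeps only its lower bound and the
#' duplication ratio only its upper bound, matching how those metrics are
#' used. Species-agnostic global rows (Q30 fraction, coverage, taxonomic
#' purity, duplicated MLST alleles, core-gene completeness/duplication) are
#' appended.
#'
#' @param taxa list from [panel_taxa()].
#' @param n_replicates pure isolates per species.
#' @param q quantile pair.
#' @param frag_n pseudo-assembly fragmentation.
#' @param seed RNG seed.
#' @return a threshold tibble (`taxon`, `rank`, `metric`, `low`, `high`,
#'   `critical`).
#' @export
panel_thresholds <- function(taxa, n_replicates = 100L, q = c(0.05, 0.95),
                             frag_n = 40L, seed = 1L) {
  counter <- 0L
  nxt <- function() {
    counter <<- counter + 1L
    (as.integer(seed) %% 100000L) * 20011L + counter
  }
  tbl <- purrr::map_dfr(taxa, function(taxon) {
    purrr::map_dfr(seq_len(n_replicates), function(rep) {
      iso <- simulate_isolate(taxon, seed = nxt())
      contigs <- pseudo_assemble(iso, frag_n = frag_n, seed = nxt())
      st <- assembly_stats(contigs)
      aln <- map_contigs(contigs, taxon$seq)
      tibble::tibble(sample = sprintf("%s_pure_%03d", taxon$species, rep),
                     species = taxon$species, genus = taxon$genus,
                     assembly_length = st$total_length, n_contigs = st$n_contigs,
                     n50 = st$n50, gc_percent = st$gc_percent,
                     duplication_ratio = duplication_ratio(aln))
    })
  })
  thr <- derive_species_thresholds(tbl, min_n = n_replicates, q = q)
  thr <- dplyr::mutate(
    thr,
    high = dplyr::if_else(.data$metric == "n50", NA_real_, .data$high),
    low = dplyr::if_else(.data$metric == "duplication_ratio", NA_real_, .data$low),
    critical = .data$metric == "assembly_length")
  dplyr::bind_rows(
    dplyr::select(thr, "taxon", "rank", "metric", "low", "high", "critical"),
    tibble::tibble(
      taxon = "global", rank = "global",
      metric = c("q30_fraction", "coverage", "taxonomy_purity",
                 "mlst_duplicated", "core_unique_percent", "core_duplicated"),
      low = c(0.8, 20, 0.95, NA, 95, NA),
      high = c(NA, NA, NA, 0, NA, 1),
      critical = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)))
}

# All requested metric groups for one sample.
measure_sample <- function(reads, contigs, subject, schemes, index, metrics,
                           rank = "species") {
  out <- list()
  if ("reads" %in% metrics && !is.null(reads)) {
    rs <- compute_read_stats(reads, nchar(subject$seq))
    out$q30_fraction <- rs$q30_fraction
    out$coverage <- rs$est_coverage
    mf <- majority_fraction_reads(reads, index, rank)
    out$read_purity <- mf$fraction
  }
  if ("assembly" %in% metrics && !is.null(contigs)) {
    st <- assembly_stats(contigs)
    out$assembly_length <- st$total_length
    out$n_contigs <- st$n_contigs
    out$n50 <- st$n50
    out$gc_percent <- st$gc_percent
    if (!is.null(index)) {
      mfc <- majority_fraction_contigs(contigs, index, rank)
      out$contig_purity <- mfc$fraction
    }
    aln <- map_contigs(contigs, c(subject$seq, subject$plasmids$seq))
    out$duplication_ratio <- duplication_ratio(aln)
  }
  if ("typing" %in% metrics && !is.null(contigs)) {
    dup <- duplicated_alleles(call_alleles(contigs, schemes$mlst))
    out$mlst_duplicated <- dup$duplicated_loci
    cga <- core_gene_assessment(contigs, schemes$core)
    out$core_unique_percent <- cga$unique_fraction
    out$core_duplicated <- cga$duplicated_count
  }
  if ("snv" %in% metrics && !is.null(reads)) {
    cc <- detect_contamination(reads, schemes$core)
    out$snv_count <- cc$n_snvs
    out$snv_contaminated <- cc$contaminated
    out$est_contamination_percent <- cc$est_contamination_percent
  }
  tibble::as_tibble(out)
}

#' Run the synthetic contamination panel
#'
#' Simulates, for every subject species, pure (self) samples, intergenus
#' mixtures with every other panel genus, and intragenus mixtures with
#' relatives at the requested allele distances, at the given mixing ratios
#' and replicate counts; computes the requested metric groups for every
#' sample and carries the ground truth along. Fully deterministic per seed.
#'
#' @param taxa list from [panel_taxa()].
#' @param distances intragenus allele distances (0 = close/same ST).
#' @param ratios contaminant read proportions.
#' @param replicates replicates per cell.
#' @param coverage sample depth.
#' @param read_len,error_rate read simulation parameters.
#' @param subs_per_allele substitutions per changed core gene.
#' @param kinds which sample kinds to simulate.
#' @param metrics which metric groups to compute (`"reads"`, `"assembly"`,
#'   `"typing"`, `"snv"`).
#' @param frag_n,min_assembly_depth pseudo-assembly parameters.
#' @param seed RNG seed.
#' @return a metric table, one row per simulated sample, with truth columns
#'   `kind`, `relatedness`, `ratio`, `replicate`, `subject`, `genus`,
#'   `contaminant`.
#' @export
run_panel <- function(taxa, distances = c(0L, 4L, 10L),
                      ratios = c(0.10, 0.20, 0.30), replicates = 2L,
                      coverage = 50, read_len = 150L, error_rate = 0.01,
                      subs_per_allele = 3L,
                      kinds = c("self", "intergenus", "intragenus"),
                      metrics = c("reads", "assembly", "typing", "snv"),
                      frag_n = 40L, min_assembly_depth = 10, seed = 1L) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  counter <- 0L
  nxt <- function() {
    counter <<- counter + 1L
    (as.integer(seed) %% 100000L) * 20173L + counter
  }
  need_reads <- any(c("reads", "snv") %in% metrics)
  need_assembly <- any(c("assembly", "typing") %in% metrics)
  index <- if (any(c("reads", "assembly") %in% metrics)) {
    genomes <- purrr::map_dfr(taxa, function(t) {
      dplyr::bind_rows(tibble::tibble(label = t$species, seq = t$seq),
                       tibble::tibble(label = t$plasmids$label,
                                      seq = t$plasmids$seq))
    })
    taxonomy <- purrr::map_dfr(taxa, function(t) {
      tibble::tibble(label = t$species, species = t$species, genus = t$genus)
    })
    build_kmer_index(genomes, taxonomy)
  }
  cont_cov <- coverage * (max(ratios) + 0.05)
  rows <- list()
  for (subject in taxa) {
    relatives <- stats::setNames(
      lapply(distances, function(d) {
        simulate_relative(subject, d, subs_per_allele, seed = nxt())
      }), as.character(distances))
    schemes <- panel_scheme(subject, relatives)
    others <- Filter(function(t) t$genus != subject$genus, taxa)
    for (rep in seq_len(replicates)) {
      pool <- if (need_reads) {
        simulate_reads(subject, coverage, read_len, error_rate, seed = nxt())
      }
      subj_species <- subject$species
      subj_genus <- subject$genus
      truth <- function(kind, contaminant, relatedness, ratio) {
        tibble::tibble(subject = subj_species, genus = subj_genus,
                       kind = kind, contaminant = contaminant,
                       relatedness = relatedness, ratio = ratio,
                       replicate = rep)
      }
      if ("self" %in% kinds) {
        contigs <- if (need_assembly) {
          pseudo_assemble(subject, frag_n = frag_n, seed = nxt())
        }
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          truth("self", NA_character_, NA_character_, 0),
          measure_sample(pool, contigs, subject, schemes, index, metrics))
      }
      if ("intergenus" %in% kinds) {
        for (other in others) {
          cpool <- if (need_reads) {
            simulate_reads(other, cont_cov, read_len, error_rate, seed = nxt())
          }
          for (r in ratios) {
            mreads <- if (need_reads) mix_reads(pool, cpool, r, seed = nxt())
            contigs <- if (need_assembly) {
              pseudo_assemble(subject, other, r, coverage,
                              min_assembly_depth, frag_n, seed = nxt())
            }
            rows[[length(rows) + 1L]] <- dplyr::bind_cols(
              truth("intergenus", other$species, NA_character_, r),
              measure_sample(mreads, contigs, subject, schemes, index, metrics))
          }
        }
      }
      if ("intragenus" %in% kinds) {
        for (d in as.character(distances)) {
          rel <- relatives[[d]]
          ad <- as.integer(d)
          cpool <- if (need_reads) {
            simulate_reads(rel, cont_cov, read_len, error_rate, seed = nxt())
          }
          for (r in ratios) {
            mreads <- if (need_reads) mix_reads(pool, cpool, r, seed = nxt())
            contigs <- if (need_assembly) {
              pseudo_assemble(subject, rel, r, coverage,
                              min_assembly_depth, frag_n, seed = nxt())
            }
            rows[[length(rows) + 1L]] <- dplyr::bind_cols(
              truth("intragenus", rel$species,
                    categorize_relatedness(ad == 0, ad), r),
              measure_sample(mreads, contigs, subject, schemes, index, metrics))
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

outside_range <- function(value, low, high) {
  (!is.na(low) & !is.na(value) & value < low) |
    (!is.na(high) & !is.na(value) & value > high)
}

#' Per-metric sensitivity and specificity of contamination prediction
#'
#' Flags every sample per metric (value outside the species threshold range,
#' purity below the threshold, any duplicated MLST allele, more than one
#' duplicated core gene, or a positive SNV contamination call) and tabulates
#' the flag rate by metric and group: intergenus samples are grouped by
#' subject genus, intragenus samples by contaminant relatedness (averaged
#' over mixing ratios and contaminants in both cases), and pure (self)
#' samples yield a specificity.
#'
#' @param metric_table output of [run_panel()].
#' @param thresholds threshold tibble from [panel_thresholds()] (or any
#'   compatible tibble).
#' @return a tibble: `metric`, `kind`, `group`, `measure`
#'   (`"sensitivity"`/`"specificity"`), `n`, `n_flagged`, `value`.
#' @export
sensitivity_table <- function(metric_table, thresholds) {
  sp_thr <- dplyr::filter(thresholds, .data$rank == "species")
  lookup <- function(metric_name) {
    idx <- match(paste(metric_table$subject, metric_name),
                 paste(sp_thr$taxon, sp_thr$metric))
    list(low = sp_thr$low[idx], high = sp_thr$high[idx])
  }
  purity_low <- thresholds$low[thresholds$metric == "taxonomy_purity"][1]
  if (is.na(purity_low)) purity_low <- 0.95
  col <- function(nm) {
    if (nm %in% names(metric_table)) metric_table[[nm]] else NA
  }
  flags <- list()
  for (m in c("assembly_length", "n_contigs", "n50", "gc_percent",
              "duplication_ratio")) {
    if (m %in% names(metric_table)) {
      b <- lookup(m)
      flags[[m]] <- outside_range(metric_table[[m]], b$low, b$high)
    }
  }
  if ("read_purity" %in% names(metric_table)) {
    flags$read_purity <- !is.na(col("read_purity")) & col("read_purity") < purity_low
  }
  if ("contig_purity" %in% names(metric_table)) {
    flags$contig_purity <- !is.na(col("contig_purity")) & col("contig_purity") < purity_low
  }
  if ("mlst_duplicated" %in% names(metric_table)) {
    flags$mlst_duplicated <- col("mlst_duplicated") >= 1
  }
  if ("core_unique_percent" %in% names(metric_table)) {
    flags$core_unique_percent <- col("core_unique_percent") <
      thresholds$low[thresholds$metric == "core_unique_percent"][1]
  }
  if ("core_duplicated" %in% names(metric_table)) {
    flags$core_duplicated <- col("core_duplicated") >
      thresholds$high[thresholds$metric == "core_duplicated"][1]
  }
  if ("snv_contaminated" %in% names(metric_table)) {
    flags$snv_contamination <- isTRUE_vec(col("snv_contaminated"))
  }
  flag_tbl <- dplyr::bind_cols(
    metric_table[, c("kind", "genus", "relatedness")],
    tibble::as_tibble(flags))
  flag_long <- tidyr::pivot_longer(flag_tbl, -c("kind", "genus", "relatedness"),
                                   names_to = "metric", values_to = "flagged")
  flag_long <- dplyr::mutate(
    flag_long,
    group = dplyr::case_when(
      kind == "self" ~ "self",
      kind == "intergenus" ~ .data$genus,
      TRUE ~ .data$relatedness),
    measure = dplyr::if_else(.data$kind == "self", "specificity", "sensitivity"))
  flag_long |>
    dplyr::filter(!is.na(.data$flagged)) |>
    dplyr::group_by(.data$metric, .data$kind, .data$group, .data$measure) |>
    dplyr::summarise(n = dplyr::n(), n_flagged = sum(.data$flagged),
                     .groups = "drop") |>
    dplyr::mutate(value = dplyr::if_else(.data$measure == "specificity",
                                         1 - .data$n_flagged / .data$n,
                                         .data$n_flagged / .data$n))
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
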