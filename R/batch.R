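# Failure-tracking batch execution over a sample sheet, with per-sample JSON
# caching, aggregate table and a static traffic-light HTML table.

#' Batch configuration
#'
#' Bundles the databases and parameters a batch run needs. Everything is
#' optional: metrics whose inputs are missing are reported as not assessed.
#'
#' @param index a `kmer_index` for taxonomic classification.
#' @param references tibble (`label`, `species`, `genus`, `seq`) of candidate
#'   reference genomes for sketch-based reference selection, the duplication
#'   ratio and the coverage denominator fallback.
#' @param mlst_scheme a 7-gene `scheme` with profiles.
#' @param core_scheme a core `scheme` for completeness and SNV detection.
#' @param thresholds threshold tibble; defaults to [default_thresholds()].
#' @param expected_genome_length fallback coverage denominator, bp.
#' @param rank classification rank for purity metrics.
#' @param min_contig_len assembly filter, bp.
#' @param purity_threshold combined-taxonomy purity bound.
#' @param outdir output directory for per-sample JSON (enables caching),
#'   `summary.tsv` and the HTML table; `NULL` disables file output.
#' @return a named list of class `qc_config`.
#' @export
qc_config <- function(index = NULL, references = NULL, mlst_scheme = NULL,
                      core_scheme = NULL, thresholds = default_thresholds(),
                      expected_genome_length = NA_real_,
                      rank = c("species", "genus"), min_contig_len = 500L,
                      purity_threshold = 0.95, outdir = NULL) {
  structure(list(index = index, references = references,
                 mlst_scheme = mlst_scheme, core_scheme = core_scheme,
                 thresholds = thresholds,
                 expected_genome_length = expected_genome_length,
                 rank = match.arg(rank), min_contig_len = min_contig_len,
                 purity_threshold = purity_threshold, outdir = outdir),
            class = "qc_config")
}

input_checksum <- function(paths) {
  paths <- paths[!is.na(paths) & file.exists(paths)]
  if (!length(paths)) return(NA_character_)
  paste(unname(tools::md5sum(sort(paths))), collapse = ":")
}

load_sample_reads <- function(row) {
  reads <- NULL
  if (!is.na(row$fq1) && file.exists(row$fq1)) {
    reads <- read_sequences(row$fq1, "fastq")
    if (!is.na(row$fq2) && file.exists(row$fq2)) {
      r2 <- read_sequences(row$fq2, "fastq")
      reads$id <- paste0(reads$id, "/1")
      r2$id <- paste0(r2$id, "/2")
      reads <- dplyr::bind_rows(reads, r2)
    }
  }
  reads
}

# Compute all assessable metrics and the report for one sample sheet row.
sample_qc <- function(row, config, ref_sketches = NULL) {
  pipeline <- list()
  metrics <- list()
  reads <- load_sample_reads(row)
  contigs <- if (!is.na(row$assembly) && file.exists(row$assembly)) {
    read_sequences(row$assembly, "fasta")
  }
  if (is.null(reads) && is.null(contigs)) {
    stop(qc_module_error("input", "no readable inputs"))
  }

  ast <- NULL
  if (!is.null(contigs)) {
    ast <- assembly_stats(contigs, config$min_contig_len)
    if (ast$status == "no_assembly") {
      stop(qc_module_error("assembly", "no assembly (empty after length filter)"))
    }
    pipeline$assembly <- as.list(ast)
    metrics$assembly_length <- ast$total_length
    metrics$n_contigs <- ast$n_contigs
    metrics$n50 <- ast$n50
    metrics$gc_percent <- ast$gc_percent
  }

  species <- genus <- NA_character_
  ref_seq <- NULL
  if (!is.null(contigs) && !is.null(config$references) && nrow(config$references)) {
    sk <- sketch_genome(contigs)
    sel <- select_reference(sk, ref_sketches)
    ref_row <- config$references[config$references$label == sel$label, ][1, ]
    species <- ref_row$species
    genus <- ref_row$genus
    ref_seq <- ref_row$seq
    pipeline$reference_search <- list(label = sel$label,
                                     mash_distance = sel$mash_distance)
    metrics$reference <- sel$label
    metrics$mash_distance <- sel$mash_distance
    aln <- map_contigs(contigs, ref_seq)
    metrics$duplication_ratio <- duplication_ratio(aln)
    metrics$genome_fraction <- genome_fraction(aln)
  }

  if (!is.null(reads)) {
    denom <- if (!is.null(ast)) ast$total_length
             else if (!is.na(config$expected_genome_length)) config$expected_genome_length
             else if (!is.null(ref_seq)) nchar(ref_seq)
             else NA_real_
    rs <- compute_read_stats(reads, denom)
    pipeline$read_qc <- as.list(rs)
    metrics$n_reads <- rs$n_reads
    metrics$q30_fraction <- rs$q30_fraction
    metrics$coverage <- rs$est_coverage
  }

  read_purity <- contig_purity <- NA_real_
  if (!is.null(config$index)) {
    if (!is.null(reads)) {
      mf <- majority_fraction_reads(reads, config$index, config$rank)
      pipeline$classification_reads <- as.list(mf)
      read_purity <- mf$fraction
      if (is.na(species) && mf$status == "ok") {
        species <- mf$majority_taxon
        genus <- config$index$genus[config$index$genus_of_species[
          match(species, config$index$species)] + 1L]
      }
    }
    if (!is.null(contigs)) {
      mfc <- majority_fraction_contigs(contigs, config$index, config$rank)
      pipeline$classification_contigs <- as.list(mfc)
      contig_purity <- mfc$fraction
    }
  }
  metrics$read_purity <- read_purity
  metrics$contig_purity <- contig_purity
  metrics$species <- species
  metrics$genus <- genus

  if (!is.null(contigs) && !is.null(config$mlst_scheme)) {
    calls <- call_alleles(contigs, config$mlst_scheme)
    dup <- duplicated_alleles(calls)
    st <- if (!is.null(config$mlst_scheme$profiles)) {
      sequence_type(calls, config$mlst_scheme)
    } else NA_character_
    pipeline$mlst <- list(st = st, duplicated_loci = dup$duplicated_loci)
    metrics$mlst_st <- st
    metrics$mlst_duplicated <- dup$duplicated_loci
  }

  if (!is.null(contigs) && !is.null(config$core_scheme)) {
    cga <- core_gene_assessment(contigs, config$core_scheme)
    pipeline$core_genes <- as.list(cga)
    metrics$core_unique_percent <- cga$unique_fraction
    metrics$core_duplicated <- cga$duplicated_count
  }

  if (!is.null(reads) && !is.null(config$core_scheme)) {
    cc <- detect_contamination(reads, config$core_scheme)
    pipeline$snv_contamination <- as.list(cc)
    metrics$snv_count <- cc$n_snvs
    metrics$snv_contaminated <- cc$contaminated
    metrics$est_contamination_percent <- cc$est_contamination_percent
  }

  thr <- resolve_thresholds(config$thresholds, species, genus)
  statuses <- metric_statuses(metrics, thr, config$purity_threshold)
  assemble_report(row$sample, metrics, statuses,
                  metadata = list(rank = config$rank,
                                  input_checksum = input_checksum(
                                    c(row$fq1, row$fq2, row$assembly))),
                  pipeline = pipeline)
}

# Evaluate the collected metrics against resolved thresholds, including the
# combined taxonomy rule and the SNV contamination status.
metric_statuses <- function(metrics, thr, purity_threshold = 0.95) {
  num <- function(m) {
    v <- metrics[[m]]
    if (is.null(v) || !length(v)) NA_real_ else suppressWarnings(as.numeric(v))
  }
  row_of <- function(m) thr[thr$metric == m, , drop = FALSE]
  ev <- function(m, value = num(m)) {
    r <- row_of(m)
    if (!nrow(r)) return(NULL)
    tibble::tibble(metric = m,
                   status = evaluate_metric(value, r$low[1], r$high[1], r$critical[1]),
                   critical = r$critical[1])
  }
  pt <- row_of("taxonomy_purity")
  if (nrow(pt) && !is.na(pt$low[1])) purity_threshold <- pt$low[1]
  snv_status <- if (is.null(metrics$snv_contaminated)) "not-assessed"
                else if (isTRUE(metrics$snv_contaminated)) "fail" else "pass"
  dplyr::bind_rows(
    ev("q30_fraction"), ev("coverage"), ev("assembly_length"), ev("n_contigs"),
    ev("n50"), ev("gc_percent"), ev("duplication_ratio"),
    ev("core_unique_percent"), ev("core_duplicated"), ev("mlst_duplicated"),
    tibble::tibble(metric = "taxonomy",
                   status = combined_taxonomy_status(num("read_purity"),
                                                     num("contig_purity"),
                                                     purity_threshold),
                   critical = TRUE),
    tibble::tibble(metric = "snv_contamination", status = snv_status,
                   critical = TRUE))
}

qc_module_error <- function(module, reason) {
  structure(class = c("qc_module_error", "error", "condition"),
            list(message = reason, call = NULL, module = module))
}

#' Run the QC pipeline over a sample sheet
#'
#' Every sample is processed independently; module failures (for example an
#' assembly that is empty after the length filter) do not abort the batch but
#' are recorded with the failing module and reason, and the aggregate report
#' covers the surviving samples. When `config$outdir` is set, per-sample JSON
#' reports are written and reused on reruns if the input files' checksums are
#' unchanged, and an aggregate `summary.tsv` plus a static traffic-light HTML
#' table are emitted.
#'
#' @param samplesheet tibble from [read_samplesheet()].
#' @param config a [qc_config()].
#' @return a list: `reports` (named list of `qc_report`), `failed` (tibble
#'   `sample`, `module`, `reason`), `summary` (one row per surviving sample),
#'   `reused` (sample names served from cache).
#' @export
run_batch <- function(samplesheet, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  ref_sketches <- NULL
  if (!is.null(config$references) && nrow(config$references)) {
    refs <- split(config$references, config$references$label)
    ref_sketches <- lapply(refs, function(r) sketch_genome(r$seq))
  }
  json_dir <- if (!is.null(config$outdir)) file.path(config$outdir, "json")
  if (!is.null(json_dir)) dir.create(json_dir, showWarnings = FALSE, recursive = TRUE)

  reports <- list()
  reused <- character()
  failed <- tibble::tibble(sample = character(), module = character(),
                           reason = character())
  for (i in seq_len(nrow(samplesheet))) {
    row <- samplesheet[i, ]
    cache_path <- if (!is.null(json_dir)) file.path(json_dir, paste0(row$sample, ".json"))
    checksum <- input_checksum(c(row$fq1, row$fq2, row$assembly))
    if (!is.null(cache_path) && file.exists(cache_path) && !is.na(checksum)) {
      cached <- read_report_json(cache_path)
      if (identical(cached$sample$metadata$input_checksum, checksum)) {
        reports[[row$sample]] <- cached
        reused <- c(reused, row$sample)
        next
      }
    }
    res <- tryCatch(sample_qc(row, config, ref_sketches), error = identity)
    if (inherits(res, "error")) {
      failed <- dplyr::bind_rows(failed, tibble::tibble(
        sample = row$sample,
        module = if (inherits(res, "qc_module_error")) res$module else "run",
        reason = conditionMessage(res)))
      next
    }
    reports[[row$sample]] <- res
    if (!is.null(cache_path)) write_report_json(res, cache_path)
  }
  summary <- batch_summary(reports)
  if (!is.null(config$outdir)) {
    readr::write_tsv(summary, file.path(config$outdir, "summary.tsv"))
    write_html_report(reports, failed, file.path(config$outdir, "report.html"))
  }
  list(reports = reports, failed = failed, summary = summary, reused = reused)
}

# One row of selected metrics + verdict per surviving sample.
batch_summary <- function(reports) {
  if (!length(reports)) {
    return(tibble::tibble(sample = character(), verdict = character()))
  }
  purrr::map_dfr(reports, function(r) {
    m <- r$sample$summary
    num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
    chr <- function(x) if (is.null(x)) NA_character_ else as.character(x)
    tibble::tibble(
      sample = r$sample$name, verdict = r$sample$assessment$verdict,
      species = chr(m$species), q30_fraction = num(m$q30_fraction),
      coverage = num(m$coverage), assembly_length = num(m$assembly_length),
      n_contigs = num(m$n_contigs), n50 = num(m$n50),
      gc_percent = num(m$gc_percent),
      duplication_ratio = num(m$duplication_ratio),
      read_purity = num(m$read_purity), contig_purity = num(m$contig_purity),
      mlst_st = chr(m$mlst_st), mlst_duplicated = num(m$mlst_duplicated),
      core_unique_percent = num(m$core_unique_percent),
      core_duplicated = num(m$core_duplicated), snv_count = num(m$snv_count),
      snv_contaminated = isTRUE(m$snv_contaminated))
  })
}

#' Write a static traffic-light HTML table
#'
#' Per-metric statuses are colour coded green (pass), orange (warn), red
#' (fail) and grey (not assessed); failed samples are listed with their
#' failing module and reason.
#'
#' @param reports named list of `qc_report` objects.
#' @param failed tibble (`sample`, `module`, `reason`).
#' @param path output HTML path.
#' @return `path`, invisibly.
#' @export
write_html_report <- function(reports, failed, path) {
  colours <- c(pass = "#c8e6c9", warn = "#ffe0b2", fail = "#ffcdd2",
               `not-assessed` = "#eeeeee")
  metrics <- unique(unlist(lapply(reports, function(r) {
    names(r$sample$assessment$statuses)
  })))
  header <- paste0("<tr><th>sample</th><th>verdict</th>",
                   paste0("<th>", metrics, "</th>", collapse = ""), "</tr>")
  rows <- vapply(reports, function(r) {
    st <- r$sample$assessment$statuses
    cells <- vapply(metrics, function(m) {
      s <- if (is.null(st[[m]])) "not-assessed" else st[[m]]
      sprintf("<td style='background:%s'>%s</td>", colours[[s]], s)
    }, character(1))
    sprintf("<tr><td>%s</td><td style='background:%s'>%s</td>%s</tr>",
            r$sample$name,
            colours[[c(pass = "pass", warning = "warn", fail = "fail")[[
              r$sample$assessment$verdict]]]],
            r$sample$assessment$verdict, paste(cells, collapse = ""))
  }, character(1))
  fail_rows <- if (nrow(failed)) {
    paste0("<h2>Failed samples</h2><table border='1'>",
           "<tr><th>sample</th><th>module</th><th>reason</th></tr>",
           paste(sprintf("<tr><td>%s</td><td>%s</td><td>%s</td></tr>",
                         failed$sample, failed$module, failed$reason),
                 collapse = ""),
           "</table>")
  } else ""
  html <- paste0("<html><head><title>isoqc report</title></head><body>",
                 "<h1>isoqc QC report</h1><table border='1'>", header,
                 paste(rows, collapse = ""), "</table>", fail_rows,
                 "</body></html>")
  writeLines(html, path)
  invisible(path)
}
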