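# Threshold derivation, per-taxon threshold lookup, the pass/warning/fail
# decision logic, two-branch report assembly with validation/filtering, and
# failure-tracking batch execution.

#' Bundled default QC thresholds
#'
#' Species-specific ranges for assembly length, contig count, GC content, N50
#' and duplication ratio, coverage minima, core-gene completeness bounds and
#' the species-agnostic global rules (Q30 fraction, taxonomic purity,
#' duplicated core genes), as an editable tibble. Ranges are 5%/95%-quantile
#' style bounds; a missing bound means unbounded on that side.
#'
#' @return a tibble: `taxon`, `rank` (`species`/`genus`/`global`), `metric`,
#'   `low`, `high`, `critical`.
#' @export
default_thresholds <- function() {
  path <- system.file("extdata", "thresholds.tsv", package = "isoqc")
  readr::read_tsv(path, col_types = readr::cols(
    taxon = "c", rank = "c", metric = "c", low = "d", high = "d", critical = "l"))
}

#' Derive species-level metric thresholds from a metric table
#'
#' For every species with at least `min_n` samples, the threshold range of
#' each metric is the empirical `q[1]`/`q[2]` quantile interval (linear
#' interpolation, R type 7, so derived thresholds are reproducible). Species
#' below `min_n` are omitted.
#'
#' @param metric_table tibble with columns `sample`, `species`, `genus` and
#'   one numeric column per metric.
#' @param min_n minimum number of samples per species.
#' @param q lower/upper quantile probabilities.
#' @return a tibble: `taxon`, `rank = "species"`, `genus`, `metric`, `low`,
#'   `high`, `n`.
#' @export
derive_species_thresholds <- function(metric_table, min_n = 100L, q = c(0.05, 0.95)) {
  if (!nrow(metric_table)) stop("empty metric table", call. = FALSE)
  stopifnot(all(c("species", "genus") %in% names(metric_table)))
  metric_cols <- names(metric_table)[vapply(metric_table, is.numeric, logical(1))]
  metric_table |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$species, .data$genus, .data$metric) |>
    dplyr::summarise(
      low = quantile(.data$value, q[1], type = 7, names = FALSE),
      high = quantile(.data$value, q[2], type = 7, names = FALSE),
      n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n >= min_n) |>
    dplyr::transmute(taxon = .data$species, rank = "species", genus = .data$genus,
                     metric = .data$metric, low = .data$low, high = .data$high,
                     n = .data$n)
}

#' Derive genus-wide thresholds from species ranges
#'
#' The genus interval spans its species: the minimum of the species lower
#' bounds to the maximum of the species upper bounds, reflecting intra-genus
#' diversity. Every member species range is contained in the genus range.
#'
#' @param species_ranges output of [derive_species_thresholds()] (must carry a
#'   `genus` column).
#' @return a tibble: `taxon` (genus), `rank = "genus"`, `metric`, `low`,
#'   `high`, `n_species`.
#' @export
derive_genus_thresholds <- function(species_ranges) {
  stopifnot(all(c("genus", "metric", "low", "high") %in% names(species_ranges)))
  species_ranges |>
    dplyr::group_by(.data$genus, .data$metric) |>
    dplyr::summarise(low = min(.data$low), high = max(.data$high),
                     n_species = dplyr::n(), .groups = "drop") |>
    dplyr::transmute(taxon = .data$genus, rank = "genus", metric = .data$metric,
                     low = .data$low, high = .data$high,
                     n_species = .data$n_species)
}

#' Resolve thresholds for one sample's taxon
#'
#' Lookup order is species, then genus, then the species-agnostic global
#' rows; a taxon without any matching threshold row simply skips those
#' taxon-specific checks.
#'
#' @param thresholds threshold tibble (`taxon`, `rank`, `metric`, `low`,
#'   `high`, `critical`).
#' @param species,genus the sample's classified taxon (either may be `NA`).
#' @return one threshold row per metric.
#' @export
resolve_thresholds <- function(thresholds, species = NA, genus = NA) {
  pick <- dplyr::bind_rows(
    if (!is.na(species)) dplyr::filter(thresholds, .data$rank == "species",
                                       .data$taxon == species),
    if (!is.na(genus)) dplyr::filter(thresholds, .data$rank == "genus",
                                     .data$taxon == genus),
    dplyr::filter(thresholds, .data$rank == "global"))
  dplyr::distinct(pick, .data$metric, .keep_all = TRUE)
}

#' Evaluate one metric value against its thresholds
#'
#' Critical metrics fail outside the `[low, high]` range (inclusive bounds;
#' `NA` bounds are unbounded) and warn when inside the fail range but outside
#' an optional nested warn range; warn-only metrics warn outside their range.
#' Missing values are not assessed.
#'
#' @param value the metric value (`NA` = not assessed).
#' @param low,high fail-range bounds.
#' @param critical is the metric critical (fail-capable)?
#' @param warn_low,warn_high optional warn-range bounds nested in the fail
#'   range (defaults collapse the warn tier onto the fail range).
#' @return `"pass"`, `"warn"`, `"fail"` or `"not-assessed"`.
#' @export
evaluate_metric <- function(value, low = NA, high = NA, critical = TRUE,
                            warn_low = NA, warn_high = NA) {
  if (is.na(value)) return("not-assessed")
  outside <- function(lo, hi) {
    (!is.na(lo) && value < lo) || (!is.na(hi) && value > hi)
  }
  if (!critical) return(if (outside(low, high)) "warn" else "pass")
  if (outside(low, high)) return("fail")
  if (outside(warn_low, warn_high)) return("warn")
  "pass"
}

#' Combined read- and contig-level taxonomy status
#'
#' The two classifications are complementary: the read-level fraction is
#' sensitive to low-level contamination but biased by multi-copy plasmids,
#' which the contig-level fraction corrects. The combined status therefore
#' fails only when both fractions fall below the purity threshold, warns when
#' exactly one does, and lets a single assessed value decide alone.
#'
#' @param read_fraction,contig_fraction majority-taxon fractions in `[0, 1]`
#'   (`NA` = not assessed).
#' @param purity_threshold the purity bound.
#' @return `"pass"`, `"warn"`, `"fail"` or `"not-assessed"`.
#' @export
combined_taxonomy_status <- function(read_fraction, contig_fraction,
                                     purity_threshold = 0.95) {
  below <- c(read_fraction, contig_fraction) < purity_threshold
  below <- below[!is.na(below)]
  if (!length(below)) return("not-assessed")
  if (all(below)) return("fail")
  if (any(below)) return("warn")
  "pass"
}

#' Aggregate per-metric statuses into a sample verdict
#'
#' A sample fails when any critical metric fails; it gets a warning when
#' nothing fails but at least one metric warns; otherwise it passes.
#' Not-assessed metrics do not influence the verdict.
#'
#' @param statuses tibble with columns `metric`, `status`, `critical`.
#' @return `"pass"`, `"warning"` or `"fail"`.
#' @export
qc_verdict <- function(statuses) {
  stopifnot(all(c("metric", "status", "critical") %in% names(statuses)))
  if (any(statuses$critical & statuses$status == "fail")) return("fail")
  if (any(statuses$status %in% c("warn", "fail"))) return("warning")
  "pass"
}

#' Assemble a two-branch QC report
#'
#' The `"pipeline"` branch stores unaltered per-module results; the
#' `"sample"` branch holds run metadata, the metric summary and the QC
#' assessment (per-metric statuses and the verdict).
#'
#' @param sample sample name.
#' @param metrics named list (or one-row tibble) of metric values.
#' @param statuses status tibble (`metric`, `status`, `critical`).
#' @param metadata named list of run metadata (tool version, parameters,
#'   database identifiers).
#' @param pipeline named list of raw per-module results.
#' @return a `qc_report`.
#' @export
assemble_report <- function(sample, metrics, statuses, metadata = list(),
                            pipeline = list()) {
  if (is.data.frame(metrics)) metrics <- as.list(metrics)
  structure(list(
    pipeline = pipeline,
    sample = list(
      name = sample,
      metadata = c(list(tool = "isoqc",
                        version = as.character(utils::packageVersion("isoqc"))),
                   metadata),
      summary = metrics,
      assessment = list(
        statuses = stats::setNames(as.list(statuses$status), statuses$metric),
        critical = stats::setNames(as.list(statuses$critical), statuses$metric),
        verdict = qc_verdict(statuses))
    )), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> sample '%s': %s\n", x$sample$name,
              x$sample$assessment$verdict))
  st <- unlist(x$sample$assessment$statuses)
  if (length(st)) {
    cat(paste0("  ", format(names(st)), "  ", st, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) {
  st <- x$sample$assessment$statuses
  cr <- x$sample$assessment$critical
  vals <- x$sample$summary
  tibble::tibble(
    metric = names(st),
    value = vapply(names(st), function(m) {
      v <- vals[[m]]
      if (is.null(v) || !is.numeric(v)) NA_real_ else as.numeric(v)
    }, numeric(1), USE.NAMES = FALSE),
    status = unlist(st, use.names = FALSE),
    critical = unlist(cr, use.names = FALSE)
  )
}

#' @export
glance.qc_report <- function(x, ...) {
  st <- unlist(x$sample$assessment$statuses)
  tibble::tibble(
    sample = x$sample$name,
    verdict = x$sample$assessment$verdict,
    n_fail = sum(st == "fail"),
    n_warn = sum(st == "warn"),
    n_not_assessed = sum(st == "not-assessed")
  )
}

#' Validate a QC report's mandatory structure
#'
#' Checks the two-branch contract: exactly the top-level branches
#' `"pipeline"` and `"sample"`, a sample name, a metric summary, and an
#' assessment with per-metric statuses and a valid verdict. Violations are
#' returned, not thrown.
#'
#' @param report a `qc_report` (or plain list read from JSON).
#' @return a tibble with column `violation` (zero rows when valid).
#' @export
validate_report <- function(report) {
  v <- character()
  if (!is.list(report)) {
    return(tibble::tibble(violation = "report is not a list"))
  }
  if (!setequal(names(report), c("pipeline", "sample"))) {
    v <- c(v, "top level must have exactly the branches 'pipeline' and 'sample'")
  }
  s <- report$sample
  if (is.null(s$name)) v <- c(v, "missing sample name")
  if (is.null(s$summary)) v <- c(v, "missing sample summary")
  if (is.null(s$assessment$statuses)) v <- c(v, "missing assessment statuses")
  verdict <- s$assessment$verdict
  if (is.null(verdict) || !verdict %in% c("pass", "warning", "fail")) {
    v <- c(v, "missing or invalid verdict")
  }
  bad <- setdiff(unlist(s$assessment$statuses),
                 c("pass", "warn", "fail", "not-assessed"))
  if (length(bad)) v <- c(v, paste("invalid status value(s):", paste(bad, collapse = ", ")))
  tibble::tibble(violation = v)
}

#' Identity filter schema of a report
#'
#' @param report a `qc_report` or nested list.
#' @return a nested list mirroring the report, with `TRUE` leaves; passing it
#'   to [filter_report()] reproduces the report unchanged.
#' @export
report_schema <- function(report) {
  walk <- function(x) {
    if (is.list(x) && length(x) && !is.null(names(x))) lapply(x, walk) else TRUE
  }
  walk(unclass(report))
}

#' Prune report branches by a filter schema
#'
#' Nodes absent from the filter schema are removed from the report; a schema
#' leaf (anything that is not a named list) keeps the whole subtree below it.
#' Filtering with the identity schema is the identity, and filtering is
#' idempotent. Intended for sharing reduced reports.
#'
#' @param report a `qc_report`.
#' @param filter_schema nested named list (see [report_schema()]).
#' @return the pruned `qc_report`.
#' @export
filter_report <- function(report, filter_schema) {
  walk <- function(x, s) {
    if (!is.list(x) || is.null(names(x)) || !is.list(s)) return(x)
    keep <- intersect(names(x), names(s))
    stats::setNames(lapply(keep, function(nm) walk(x[[nm]], s[[nm]])), keep)
  }
  structure(walk(unclass(report), filter_schema), class = "qc_report")
}
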