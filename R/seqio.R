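# File input/output: FASTA, FASTQ (Phred+33), sample sheets, scheme
# directories and report JSON. The only module that touches files.

#' Read sequences from FASTA or FASTQ
#'
#' Sequences are returned as a tibble with one row per record: `id` (the header
#' up to the first whitespace), `seq` (upper-cased, with any character outside
#' ACGTN mapped to N) and `qual` (the Phred+33 quality string for FASTQ, `NA`
#' for FASTA). Gzip-compressed files are decompressed transparently. Quality
#' encoding is fixed to Phred+33; no auto-detection is attempted.
#'
#' @param path path to the sequence file.
#' @param format `"auto"` (by file extension), `"fasta"` or `"fastq"`.
#' @return a tibble with columns `id`, `seq`, `qual`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) "fastq" else "fasta"
  }
  out <- if (format == "fastq") read_fastq_impl(path) else read_fasta_impl(path)
  if (anyDuplicated(out$id)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(out$seq))) stop("empty sequence record in ", path, call. = FALSE)
  out
}

read_fasta_impl <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    return(tibble::tibble(id = character(), seq = character(), qual = character()))
  }
  ids <- sub("\\s.*$", "", names(set))
  tibble::tibble(id = ids, seq = normalise_seq(as.character(set)),
                 qual = NA_character_)
}

# Strict 4-line FASTQ reader: validates record structure and seq/qual length so
# that truncated or malformed files are reported with the offending line.
read_fastq_impl <- function(path) {
  lines <- readr::read_lines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop(sprintf("truncated FASTQ: %d lines is not a multiple of 4 (near line %d) in %s",
                 n, n, path), call. = FALSE)
  }
  if (n == 0) return(tibble::tibble(id = character(), seq = character(), qual = character()))
  hdr <- lines[seq(1L, n, 4L)]
  seqs <- lines[seq(2L, n, 4L)]
  plus <- lines[seq(3L, n, 4L)]
  qual <- lines[seq(4L, n, 4L)]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    stop(sprintf("malformed FASTQ record: header does not start with '@' at line %d in %s",
                 (bad_hdr[1] - 1L) * 4L + 1L, path), call. = FALSE)
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    stop(sprintf("malformed FASTQ record: separator line is not '+' at line %d in %s",
                 (bad_plus[1] - 1L) * 4L + 3L, path), call. = FALSE)
  }
  bad_len <- which(nchar(seqs) != nchar(qual))
  if (length(bad_len)) {
    stop(sprintf("malformed FASTQ record: sequence and quality lengths differ at line %d in %s",
                 (bad_len[1] - 1L) * 4L + 2L, path), call. = FALSE)
  }
  tibble::tibble(id = sub("\\s.*$", "", sub("^@", "", hdr)),
                 seq = normalise_seq(seqs), qual = qual)
}

#' Write sequences to FASTA or FASTQ
#'
#' @param seqs a sequence tibble (`id`, `seq`, and `qual` for FASTQ).
#' @param path output path.
#' @param width line width for FASTA wrapping (FASTQ is always unwrapped).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  check_seq_tbl(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$id[i]), con)
    s <- seqs$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(seqs, path) {
  check_seq_tbl(seqs, need_qual = TRUE)
  lines <- as.vector(rbind(paste0("@", seqs$id), seqs$seq, "+", seqs$qual))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sheet is a TSV with header `sample`, `fq1`, `fq2`, `assembly`; empty
#' cells are allowed, and relative paths are resolved against the sheet's
#' directory. Each row must name at least reads or an assembly; duplicate
#' sample names are an error. Paths pointing to missing files are collected
#' into the `"file_warnings"` attribute (and raised as a warning) rather than
#' failing, so that batch runs can report them per sample.
#'
#' @param path path to the TSV sample sheet.
#' @return a tibble with columns `sample`, `fq1`, `fq2`, `assembly`.
#' @export
read_samplesheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  for (col in c("sample", "fq1", "fq2", "assembly")) {
    if (!col %in% names(sheet)) sheet[[col]] <- NA_character_
  }
  sheet <- sheet[, c("sample", "fq1", "fq2", "assembly")]
  if (anyNA(sheet$sample)) stop("sample sheet has rows without a sample name", call. = FALSE)
  if (anyDuplicated(sheet$sample)) {
    stop("duplicate sample name(s): ",
         paste(unique(sheet$sample[duplicated(sheet$sample)]), collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(is.na(p) | p == "" | grepl("^/", p), dplyr::na_if(p, ""),
           file.path(base, p))
  }
  sheet <- dplyr::mutate(sheet, dplyr::across(c("fq1", "fq2", "assembly"), resolve))
  no_input <- is.na(sheet$fq1) & is.na(sheet$assembly)
  if (any(no_input)) {
    stop("sample(s) with neither reads nor assembly: ",
         paste(sheet$sample[no_input], collapse = ", "), call. = FALSE)
  }
  paths <- stats::na.omit(unlist(sheet[, c("fq1", "fq2", "assembly")]))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    warning("sample sheet references missing file(s): ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  attr(sheet, "file_warnings") <- unname(missing)
  sheet
}

#' Write and re-read a QC report as JSON
#'
#' The on-disk layout has exactly two top-level branches: `"pipeline"` (raw
#' per-module results) and `"sample"` (run configuration, metric summary and
#' QC assessment). Writing validates the report first; reading restores the
#' `qc_report` object, and a write/read cycle is stable.
#'
#' @param report a `qc_report` object (see [assemble_report()]).
#' @param path output path.
#' @return `path` invisibly for the writer; a `qc_report` for the reader.
#' @export
write_report_json <- function(report, path) {
  v <- validate_report(report)
  if (nrow(v)) {
    stop("invalid report: ", paste(v$violation, collapse = "; "), call. = FALSE)
  }
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  structure(x, class = "qc_report")
}
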