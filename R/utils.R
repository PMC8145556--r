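# Small shared helpers.

#' Reverse complement of nucleotide strings
#'
#' Vectorised over its input. Characters other than A/C/G/T (upper case) are
#' complemented to N.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgtNn", "TGCATGCANN", x))
}

#' Decode Phred+33 quality strings
#'
#' @param qual character vector of Phred+33 encoded quality strings.
#' @return list of integer vectors of per-base Phred scores.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q)) return(NULL)
    utf8ToInt(q) - 33L
  })
}

#' Encode integer Phred scores as a Phred+33 string
#'
#' @param scores integer vector of Phred scores (all >= 0).
#' @return single character string.
#' @export
phred_encode <- function(scores) {
  stopifnot(all(scores >= 0L))
  intToUtf8(as.integer(scores) + 33L)
}

# Normalise a nucleotide string: upper case, anything outside ACGTN becomes N.
normalise_seq <- function(x) {
  stringr::str_replace_all(toupper(x), "[^ACGTN]", "N")
}

# Evaluate `expr` under a fixed seed when `seed` is non-NULL, otherwise in the
# current RNG state.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Assert that `x` looks like a sequence table (id, seq [, qual]).
check_seq_tbl <- function(x, need_qual = FALSE, arg = deparse(substitute(x))) {
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    stop(sprintf("`%s` must be a data frame with columns `id` and `seq`", arg),
         call. = FALSE)
  }
  if (need_qual && (!"qual" %in% names(x) || anyNA(x$qual))) {
    stop(sprintf("`%s` must carry per-read qualities in column `qual`", arg),
         call. = FALSE)
  }
  invisible(x)
}
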