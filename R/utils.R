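# Shared low-level helpers.

#' Reverse complement of DNA strings
#'
#' Case-preserving reverse complement over the IUPAC alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- chartr(
    "ACGTMRWSYKVHDBNacgtmrwsykvhdbn",
    "TGCAKYWSRMBDHVNtgcakywsrmbdhvn",
    x
  )
  vapply(strsplit(out, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Round half away from zero
#'
#' The convention used for printed percentages in motif tables (base
#' `round()` is banker's rounding).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a contig collection: named character vector, unique non-empty ids,
# IUPAC letters only.
assert_contigs <- function(seqs, what = "contigs") {
  if (!is.character(seqs)) stop(what, " must be a character vector", call. = FALSE)
  ids <- names(seqs)
  if (length(seqs) > 0L && (is.null(ids) || any(!nzchar(ids)) || anyNA(ids)))
    stop(what, ": every sequence needs a non-empty id (names attribute)", call. = FALSE)
  if (anyDuplicated(ids))
    stop(what, ": duplicate ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  bad <- grepl("[^ACGTMRWSYKVHDBNacgtmrwsykvhdbn]", seqs)
  if (any(bad))
    stop(what, ": non-IUPAC characters in sequence(s): ",
         paste(utils::head(ids[bad], 5L), collapse = ", "), call. = FALSE)
  invisible(seqs)
}

# Integer-ish scalar check.
assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x) || x < min)
    stop(name, " must be a single integer >= ", min, call. = FALSE)
  as.integer(x)
}
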