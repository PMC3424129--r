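# Sequence input/output and composition primitives.
#
# Contigs are represented as a named character vector: names are the unique
# ids (the FASTA header token before the first whitespace), values the
# sequences with case preserved. Lowercase encodes masked bases (cross_match
# style); N is treated as masked for trimming and is never counted in GC
# composition. All coordinates in this package are 1-based inclusive.

#' Read a FASTA file into a named character vector
#'
#' Case is preserved (lowercase = masked). The id is the header token before
#' the first whitespace; the remainder of the header is kept in the
#' `"descriptions"` attribute.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (possibly empty, with a
#'   warning, for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  line_no <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(structure(character(0), descriptions = character(0)))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L])
    stop("malformed FASTA at line ", line_no[1L],
         ": sequence data before first header", call. = FALSE)
  rec <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) {
    bad <- line_no[is_hdr][!nzchar(ids)][1L]
    stop("malformed FASTA at line ", bad, ": empty record id", call. = FALSE)
  }
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  body <- lines
  body[is_hdr] <- ""
  seqs <- vapply(split(body, rec), paste, character(1), collapse = "")
  names(seqs) <- ids
  bad_char <- grepl("[^ACGTMRWSYKVHDBNacgtmrwsykvhdbn]", seqs)
  if (any(bad_char)) {
    i <- which(bad_char)[1L]
    stop("malformed FASTA record '", ids[i], "' (header at line ",
         line_no[is_hdr][i], "): non-IUPAC characters", call. = FALSE)
  }
  structure(seqs, descriptions = stats::setNames(desc, ids))
}

#' Write contigs to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 80).
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  assert_contigs(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s) == 0L) next
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a phred-style quality file
#'
#' Returns one integer vector of per-base quality values per record.
#' Quality values are informational only; no operation in the package
#' consumes them.
#'
#' @param path path to a `.qual` file (FASTA-like headers, whitespace
#'   separated integers).
#' @return named list of integer vectors.
#' @export
read_quality <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) return(list())
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) stop("malformed quality file: data before header", call. = FALSE)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[is_hdr]))
  rec <- cumsum(is_hdr)
  body <- lines
  body[is_hdr] <- ""
  vals <- lapply(split(body, rec), function(x)
    as.integer(scan(text = paste(x, collapse = " "), quiet = TRUE)))
  stats::setNames(vals, ids)
}

#' Extract the longest unmasked region of each contig
#'
#' Masked bases are lowercase letters and N (either case). The longest
#' contiguous run of unmasked bases is returned; ties are broken by the
#' leftmost start. Ids gain a `:start-end` suffix only when trimming removed
#' something, so the operation is idempotent. Fully masked contigs yield an
#' empty sequence and are flagged in the `"excluded"` attribute.
#'
#' @param seqs named character vector of sequences.
#' @return named character vector with attributes `regions`
#'   (data.frame: id, start, end) and `excluded` (logical vector).
#' @export
longest_unmasked_region <- function(seqs) {
  assert_contigs(seqs)
  n <- length(seqs)
  out <- character(n)
  starts <- integer(n)
  ends <- integer(n)
  excluded <- logical(n)
  ids <- names(seqs)
  new_ids <- ids
  for (i in seq_len(n)) {
    m <- gregexpr("[A-MO-Z]+", seqs[[i]])[[1L]]
    if (m[1L] == -1L) {
      out[i] <- ""
      starts[i] <- NA_integer_
      ends[i] <- NA_integer_
      excluded[i] <- TRUE
      next
    }
    lens <- attr(m, "match.length")
    j <- which.max(lens)  # leftmost maximal run
    starts[i] <- as.integer(m[j])
    ends[i] <- as.integer(m[j]) + lens[j] - 1L
    out[i] <- substr(seqs[[i]], starts[i], ends[i])
    if (starts[i] != 1L || ends[i] != nchar(seqs[[i]]))
      new_ids[i] <- paste0(ids[i], ":", starts[i], "-", ends[i])
  }
  names(out) <- new_ids
  structure(out,
            regions = data.frame(id = ids, start = starts, end = ends,
                                 stringsAsFactors = FALSE),
            excluded = stats::setNames(excluded, ids))
}

#' Drop contigs shorter than a minimum length
#'
#' @param seqs named character vector.
#' @param min_len minimum retained length in bp (default 100, the standard
#'   validity cutoff for cleaned EST reads).
#' @return filtered vector; discarded ids in the `"discards"` attribute
#'   (data.frame: id, length, reason).
#' @export
min_length_filter <- function(seqs, min_len = 100L) {
  min_len <- assert_count(min_len, "min_len", min = 1L)
  assert_contigs(seqs)
  len <- nchar(seqs)
  drop <- len < min_len
  if (any(drop))
    message(sum(drop), " contig(s) shorter than ", min_len, " bp discarded")
  structure(seqs[!drop],
            discards = data.frame(id = names(seqs)[drop],
                                  length = unname(len[drop]),
                                  reason = if (any(drop)) "short" else character(0),
                                  stringsAsFactors = FALSE))
}

#' Write a discard log as TSV
#'
#' @param discards data.frame with at least columns id and reason (the
#'   `"discards"` attribute of [min_length_filter()] fits).
#' @param path output path.
#' @export
write_discards <- function(discards, path) {
  utils::write.table(discards[, c("id", "reason")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' GC percentage of a contig
#'
#' 100 * (G+C) / (A+C+G+T) over bases outside `mask`. N and IUPAC ambiguity
#' codes are excluded from both numerator and denominator; lowercase a/c/g/t
#' count as ordinary bases (soft masking is a trimming concern, not a
#' composition one). With no countable base the value is undefined and NA is
#' returned with a warning.
#'
#' @param seq a single sequence string.
#' @param mask optional data.frame/matrix with columns start, end (1-based
#'   inclusive intervals to exclude, e.g. the SSR region itself).
#' @return numeric percentage in \[0, 100\], or NA.
#' @export
gc_percent <- function(seq, mask = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (!is.null(mask) && NROW(mask) > 0L) {
    mask <- as.data.frame(mask)
    st <- as.integer(mask[[1L]]); en <- as.integer(mask[[2L]])
    if (any(is.na(st)) || any(is.na(en)) || any(st < 1L) ||
        any(en > nchar(s)) || any(st > en))
      stop("mask intervals out of bounds", call. = FALSE)
    keep <- rep(TRUE, nchar(s))
    for (i in seq_along(st)) keep[st[i]:en[i]] <- FALSE
    s <- paste(strsplit(s, "", fixed = TRUE)[[1L]][keep], collapse = "")
  }
  gc <- nchar(gsub("[^GC]", "", s))
  acgt <- nchar(gsub("[^ACGT]", "", s))
  if (acgt == 0L) {
    warning("gc_percent undefined: no countable bases", call. = FALSE)
    return(NA_real_)
  }
  100 * gc / acgt
}
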