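# Coding-region coordinates and genic location of SSR loci.
#
# Coding coordinates are an input contract: supply them as a 4-column TSV or
# GFF3 CDS lines, or fall back on the declared open-reading-frame stand-in
# below (which replaces a full peptide-prediction pipeline and records its
# provenance in the `source` field). One CDS interval per contig.

#' Find the longest open reading frame across six frames
#'
#' An ORF is a run of codons free of TAA/TAG/TGA (codons containing non-ACGT
#' bases are treated as non-stop); the trailing stop codon, when present, is
#' included in the reported CDS. ORFs found on the minus strand are reported
#' with `strand = "-"` and coordinates on the reverse-complemented
#' orientation. Ties prefer the plus strand, then the smallest start.
#'
#' @param seq a single contig sequence (treated case-insensitively).
#' @param min_codons minimum ORF length in codons, stop excluded
#'   (default 30); shorter ORFs return NULL.
#' @param require_atg if TRUE the ORF must begin with ATG (default FALSE).
#' @return list(cds_start, cds_end, strand, source = "orf_standin") or NULL.
#' @export
find_longest_orf <- function(seq, min_codons = 30L, require_atg = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  min_codons <- assert_count(min_codons, "min_codons", 1L)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- toupper(if (strand == "+") seq else revcomp(seq))
    n <- nchar(s)
    for (off in 0:2) {
      starts <- seq(1L + off, n - 2L, by = 3L)
      if (length(starts) == 0L) next
      codons <- substring(s, starts, starts + 2L)
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      r <- rle(!is_stop)
      ends_i <- cumsum(r$lengths)
      starts_i <- ends_i - r$lengths + 1L
      for (j in which(r$values)) {
        i0 <- starts_i[j]; i1 <- ends_i[j]
        if (require_atg) {
          atg <- which(codons[i0:i1] == "ATG")
          if (length(atg) == 0L) next
          i0 <- i0 + atg[1L] - 1L
        }
        len <- i1 - i0 + 1L
        if (len < min_codons) next
        cds_end <- starts[i1] + 2L
        # include the trailing stop codon when one follows the run
        has_stop <- i1 < length(codons) && is_stop[i1 + 1L]
        if (has_stop) cds_end <- cds_end + 3L
        # rank by total CDS length (stop included); ties prefer a
        # stop-terminated ORF, then the plus strand, then the smallest start
        cand <- list(cds_start = starts[i0], cds_end = cds_end,
                     strand = strand, source = "orf_standin",
                     cds_len = cds_end - starts[i0] + 1L,
                     has_stop = has_stop)
        if (is.null(best) || cand$cds_len > best$cds_len ||
            (cand$cds_len == best$cds_len && cand$has_stop && !best$has_stop))
          best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  best[c("cds_start", "cds_end", "strand", "source")]
}

#' Annotate a contig collection with the ORF stand-in
#'
#' @param seqs named character vector of contigs.
#' @inheritParams find_longest_orf
#' @return data.frame with columns contig_id, cds_start, cds_end, strand,
#'   source; contigs without a qualifying ORF are absent.
#' @export
annotate_orfs <- function(seqs, min_codons = 30L, require_atg = FALSE) {
  assert_contigs(seqs)
  rows <- lapply(seq_along(seqs), function(i) {
    orf <- find_longest_orf(seqs[[i]], min_codons, require_atg)
    if (is.null(orf)) return(NULL)
    data.frame(contig_id = names(seqs)[i], cds_start = orf$cds_start,
               cds_end = orf$cds_end, strand = orf$strand,
               source = orf$source, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(contig_id = character(0), cds_start = integer(0),
                      cds_end = integer(0), strand = character(0),
                      source = character(0), stringsAsFactors = FALSE)
  out
}

#' Read coding-region annotations
#'
#' Accepts either a 4-column TSV (contig_id, cds_start, cds_end, strand;
#' header optional) or a GFF3 file whose CDS lines are used. Exactly one CDS
#' interval per contig; multi-interval annotations are rejected.
#'
#' @param path input path.
#' @return data.frame with columns contig_id, cds_start, cds_end, strand,
#'   source = "user".
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  gff <- any(startsWith(lines, "##gff-version")) ||
    any(grepl("\t(CDS)\t", lines))
  if (gff) {
    lines <- lines[!startsWith(lines, "#")]
    f <- strsplit(lines, "\t", fixed = TRUE)
    f <- f[vapply(f, length, integer(1)) >= 8L]
    f <- f[vapply(f, function(x) x[3L] == "CDS", logical(1))]
    out <- data.frame(
      contig_id = vapply(f, `[`, character(1), 1L),
      cds_start = as.integer(vapply(f, `[`, character(1), 4L)),
      cds_end = as.integer(vapply(f, `[`, character(1), 5L)),
      strand = vapply(f, `[`, character(1), 7L),
      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("contig_id", "cds_start",
                                           "cds_end", "strand"))
    if (identical(tolower(out$contig_id[1L]), "contig_id"))
      out <- out[-1L, , drop = FALSE]
    out$cds_start <- as.integer(out$cds_start)
    out$cds_end <- as.integer(out$cds_end)
  }
  if (anyDuplicated(out$contig_id))
    stop("multi-interval CDS annotation for contig(s): ",
         paste(unique(out$contig_id[duplicated(out$contig_id)]),
               collapse = ", "), call. = FALSE)
  if (any(is.na(out$cds_start)) || any(is.na(out$cds_end)) ||
      any(out$cds_start < 1L) || any(out$cds_start > out$cds_end))
    stop("invalid CDS coordinates in ", path, call. = FALSE)
  if (!all(out$strand %in% c("+", "-")))
    stop("strand must be + or -", call. = FALSE)
  out$source <- "user"
  rownames(out) <- NULL
  out
}

#' Classify an SSR locus relative to a coding region
#'
#' Both locus and annotation are taken in the same (sense) orientation.
#' Containment is inclusive: a locus touching a CDS boundary base without
#' crossing it is coding.
#'
#' @param start,end 1-based inclusive locus coordinates (vectors recycle).
#' @param cds_start,cds_end CDS interval; pass NA for an unannotated contig.
#' @param contig_length optional, enables bounds checking.
#' @return character vector over \{"five_prime_utr", "coding",
#'   "three_prime_utr", "undetermined", "no_annotation"\}.
#' @export
classify_location <- function(start, end, cds_start, cds_end,
                              contig_length = NULL) {
  n <- max(length(start), length(end), length(cds_start), length(cds_end))
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  cds_start <- rep_len(as.integer(cds_start), n)
  cds_end <- rep_len(as.integer(cds_end), n)
  if (any(start < 1L) || any(start > end))
    stop("invalid locus coordinates", call. = FALSE)
  if (!is.null(contig_length)) {
    contig_length <- rep_len(as.integer(contig_length), n)
    if (any(end > contig_length))
      stop("locus coordinates out of contig bounds", call. = FALSE)
  }
  out <- rep("undetermined", n)
  none <- is.na(cds_start) | is.na(cds_end)
  out[!none & end < cds_start] <- "five_prime_utr"
  out[!none & start >= cds_start & end <= cds_end] <- "coding"
  out[!none & start > cds_end] <- "three_prime_utr"
  out[none] <- "no_annotation"
  out
}

#' Attach location calls to a locus table
#'
#' @param loci result of [detect_ssrs()].
#' @param annotations data.frame as returned by [read_annotations()] or
#'   [annotate_orfs()].
#' @param contig_lengths optional named integer vector for bounds checking.
#' @return `loci` with an added `location` column.
#' @export
classify_loci <- function(loci, annotations, contig_lengths = NULL) {
  idx <- match(loci$contig_id, annotations$contig_id)
  loci$location <- classify_location(
    loci$start, loci$end,
    annotations$cds_start[idx], annotations$cds_end[idx],
    if (!is.null(contig_lengths)) contig_lengths[loci$contig_id])
  loci
}

#' Write location calls as TSV
#'
#' @param loci locus table carrying a `location` column.
#' @param path output path.
#' @export
write_locations <- function(loci, path) {
  out <- data.frame(locus = paste0(loci$contig_id, ".ssr", loci$ssr_nr),
                    location = loci$location, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
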