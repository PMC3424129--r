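# SSR-flanking primer pair enumeration.
#
# A transparent stand-in for a full thermodynamic primer designer: every
# candidate pair satisfying the declared length, Tm, GC, homopolymer,
# dimer and product-size constraints is enumerated and ranked by a simple
# penalty against the optima. The ranking is a total order, so repeated
# runs give identical output.

#' Primer design constraints
#'
#' @param primer_len length range in bp, `c(min, max)` (default 18-24).
#' @param primer_opt optimum primer length (default 20).
#' @param tm melting temperature range in deg C (default 57-63).
#' @param tm_opt optimum Tm (default 60).
#' @param gc GC percentage range (default 30-70).
#' @param product_size amplicon size range in bp (default 100-400).
#' @param max_homopolymer longest tolerated single-base run (default 4).
#' @param max_product_report products longer than this are flagged oversize
#'   (default 600 bp, the practical sizing limit of capillary
#'   electrophoresis).
#' @param dimer_len minimum perfect self/cross-dimer (reverse-complement
#'   match) length that rejects a pair (default 8).
#' @return list of class `design_constraints`.
#' @export
design_constraints <- function(primer_len = c(18L, 24L), primer_opt = 20L,
                               tm = c(57, 63), tm_opt = 60,
                               gc = c(30, 70),
                               product_size = c(100L, 400L),
                               max_homopolymer = 4L,
                               max_product_report = 600L,
                               dimer_len = 8L) {
  stopifnot(length(primer_len) == 2L, primer_len[1L] <= primer_len[2L],
            primer_opt >= primer_len[1L], primer_opt <= primer_len[2L],
            length(tm) == 2L, tm[1L] <= tm[2L],
            tm_opt >= tm[1L], tm_opt <= tm[2L],
            length(gc) == 2L, gc[1L] <= gc[2L],
            length(product_size) == 2L,
            product_size[1L] <= product_size[2L],
            max_homopolymer >= 1L, dimer_len >= 4L)
  structure(list(primer_len = as.integer(primer_len),
                 primer_opt = as.integer(primer_opt),
                 tm = as.numeric(tm), tm_opt = as.numeric(tm_opt),
                 gc = as.numeric(gc),
                 product_size = as.integer(product_size),
                 max_homopolymer = as.integer(max_homopolymer),
                 max_product_report = as.integer(max_product_report),
                 dimer_len = as.integer(dimer_len)),
            class = "design_constraints")
}

#' Primer melting temperature
#'
#' Wallace rule 2(A+T) + 4(G+C) for primers shorter than 14 bases; the
#' GC-fraction formula 64.9 + 41 (G+C - 16.4) / length otherwise.
#'
#' @param primer character vector of ACGT primer sequences, each >= 8 bases.
#' @return numeric vector of Tm in deg C.
#' @export
melting_temperature <- function(primer) {
  primer <- toupper(primer)
  if (any(nchar(primer) < 8L)) stop("primer shorter than 8 bases", call. = FALSE)
  if (any(grepl("[^ACGT]", primer)))
    stop("primer contains non-ACGT base", call. = FALSE)
  n <- nchar(primer)
  gc <- nchar(gsub("[^GC]", "", primer))
  ifelse(n < 14L, 2 * (n - gc) + 4 * gc, 64.9 + 41 * (gc - 16.4) / n)
}

.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

# Does a share a >= k bp reverse-complement match with b (cross-dimer) or
# with itself when b == a (self-dimer)?
.has_dimer <- function(a, b, k) {
  any(revcomp(.kmers(a, k)) %in% .kmers(b, k))
}

# Enumerate single-primer candidates over windows of a template region.
# dir = "F": primer is the template substring; dir = "R": the reverse
# complement of the template substring.
.primer_candidates <- function(template, from, to, k, dir) {
  rows <- list()
  for (len in k$primer_len[1L]:k$primer_len[2L]) {
    starts <- from:(to - len + 1L)
    starts <- starts[starts >= from & (starts + len - 1L) <= to]
    if (length(starts) == 0L) next
    seqs <- substring(template, starts, starts + len - 1L)
    if (dir == "R") seqs <- revcomp(seqs)
    gc <- 100 * nchar(gsub("[^GCgc]", "", seqs)) / len
    bad <- grepl("[^ACGT]", seqs) |
      grepl(sprintf("(A{%d}|C{%d}|G{%d}|T{%d})",
                    k$max_homopolymer + 1L, k$max_homopolymer + 1L,
                    k$max_homopolymer + 1L, k$max_homopolymer + 1L), seqs) |
      gc < k$gc[1L] | gc > k$gc[2L]
    keep <- which(!bad)
    if (length(keep) == 0L) next
    tm <- melting_temperature(seqs[keep])
    ok <- tm >= k$tm[1L] & tm <= k$tm[2L]
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- data.frame(
      start = starts[keep][ok], len = len, seq = seqs[keep][ok],
      tm = tm[ok], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Enumerate and rank SSR-flanking primer pairs
#'
#' All primer pairs satisfying every constraint, with the target locus
#' strictly between the two primer footprints, ranked by
#' `|tm_f - tm_opt| + |tm_r - tm_opt| + |len_f - opt| + |len_r - opt| +
#' 0.01 |product - midpoint of product range|`; ties broken by
#' (forward_start, product size).
#'
#' @param template a single template sequence.
#' @param target list or one-row data.frame with `start` and `end` (the SSR
#'   locus, 1-based inclusive).
#' @param k a [design_constraints()].
#' @return data.frame of pairs (forward_seq, reverse_seq, forward_start,
#'   forward_end, reverse_start, reverse_end, tm_forward, tm_reverse,
#'   product_bp, penalty, oversize); zero rows carry a `reason` attribute
#'   naming the eliminating constraint.
#' @export
design_primers <- function(template, target, k = design_constraints()) {
  stopifnot(is.character(template), length(template) == 1L)
  template <- toupper(template)
  n <- nchar(template)
  t_start <- as.integer(target$start); t_end <- as.integer(target$end)
  stopifnot(t_start >= 1L, t_end >= t_start, t_end <= n)
  empty <- function(reason) {
    out <- data.frame(forward_seq = character(0), reverse_seq = character(0),
                      forward_start = integer(0), forward_end = integer(0),
                      reverse_start = integer(0), reverse_end = integer(0),
                      tm_forward = numeric(0), tm_reverse = numeric(0),
                      product_bp = integer(0), penalty = numeric(0),
                      oversize = logical(0), stringsAsFactors = FALSE)
    attr(out, "reason") <- reason
    out
  }
  if (t_start - 1L < k$primer_len[1L] || n - t_end < k$primer_len[1L])
    return(empty("insufficient flank"))
  fwd <- .primer_candidates(template, 1L, t_start - 1L, k, "F")
  if (is.null(fwd)) return(empty("no acceptable forward primer"))
  rev_ <- .primer_candidates(template, t_end + 1L, n, k, "R")
  if (is.null(rev_)) return(empty("no acceptable reverse primer"))
  # self-dimer screen per candidate, before pairing
  fwd <- fwd[!vapply(fwd$seq, function(s) .has_dimer(s, s, k$dimer_len),
                     logical(1)), , drop = FALSE]
  rev_ <- rev_[!vapply(rev_$seq, function(s) .has_dimer(s, s, k$dimer_len),
                       logical(1)), , drop = FALSE]
  if (nrow(fwd) == 0L || nrow(rev_) == 0L)
    return(empty("all pairs rejected by dimer screen"))
  # cross-dimer lookup: which reverse candidates contain each k-mer
  rev_kmer_map <- new.env(parent = emptyenv())
  for (j in seq_len(nrow(rev_))) {
    for (km in unique(.kmers(rev_$seq[j], k$dimer_len))) {
      rev_kmer_map[[km]] <- c(rev_kmer_map[[km]], j)
    }
  }
  cross_conflicts <- function(fseq) {
    hits <- unlist(lapply(unique(revcomp(.kmers(fseq, k$dimer_len))),
                          function(km) rev_kmer_map[[km]]), use.names = FALSE)
    unique(hits)
  }
  # pair within the product-size range
  pairs <- list()
  mid <- mean(k$product_size)
  rev_end_all <- rev_$start + rev_$len - 1L
  for (i in seq_len(nrow(fwd))) {
    prod <- rev_end_all - fwd$start[i] + 1L
    sel <- which(prod >= k$product_size[1L] & prod <= k$product_size[2L])
    bad <- cross_conflicts(fwd$seq[i])
    if (length(bad)) sel <- setdiff(sel, bad)
    if (length(sel) == 0L) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      forward_seq = fwd$seq[i], reverse_seq = rev_$seq[sel],
      forward_start = fwd$start[i], forward_end = fwd$start[i] + fwd$len[i] - 1L,
      reverse_start = rev_$start[sel], reverse_end = rev_end_all[sel],
      tm_forward = fwd$tm[i], tm_reverse = rev_$tm[sel],
      product_bp = prod[sel], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pairs)
  if (is.null(out)) return(empty("no feasible pair after screening"))
  out$penalty <- abs(out$tm_forward - k$tm_opt) + abs(out$tm_reverse - k$tm_opt) +
    abs(nchar(out$forward_seq) - k$primer_opt) +
    abs(nchar(out$reverse_seq) - k$primer_opt) +
    0.01 * abs(out$product_bp - mid)
  out$oversize <- out$product_bp > k$max_product_report
  out <- out[order(out$penalty, out$forward_start, out$product_bp), ]
  rownames(out) <- NULL
  out
}

#' Write designed primer pairs as TSV
#'
#' @param pairs data.frame from [design_primers()], optionally carrying
#'   locus/template id columns.
#' @param path output path.
#' @export
write_primers <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
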