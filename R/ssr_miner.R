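# Microsatellite detection and motif classification.
#
# Perfect tandem repeats of primitive 2-6 bp units are mined under per-unit-
# length minimum repeat counts (MISA thresholds: 6/5/4/3/3 for di..hexa).
# Qualifying runs lying within `max_interruption` bp of each other are merged
# into a single compound record whose constituent runs are kept as children.
#
# Detection rule, stated once: a candidate locus is a left- and right-maximal
# run of full units of a primitive unit over A/C/G/T only; candidates of the
# same unit length are accepted in ascending start order, skipping any that
# overlaps an already accepted locus of that unit length. The shortest
# primitive unit describing a run wins (a non-primitive unit is never
# reported). The brute-force enumerator in the test suite implements the same
# rule by a different algorithm.

#' Mining configuration
#'
#' @param min_repeats named integer vector mapping unit length (2-6) to the
#'   minimum number of repeats. Defaults: di 6, tri 5, tetra 4, penta 3,
#'   hexa 3.
#' @param max_interruption maximum distance in bp between two adjacent
#'   qualifying runs merged into one compound record. 0 for frequency
#'   surveys; 100 is the customary value for marker design.
#' @return list of class `mining_config`.
#' @export
mining_config <- function(min_repeats = c(`2` = 6L, `3` = 5L, `4` = 4L,
                                          `5` = 3L, `6` = 3L),
                          max_interruption = 0L) {
  min_repeats <- min_repeats[order(as.integer(names(min_repeats)))]
  k <- as.integer(names(min_repeats))
  if (!identical(k, 2:6))
    stop("min_repeats must be named with unit lengths 2..6", call. = FALSE)
  if (any(min_repeats < 2L)) stop("all minimum repeat counts must be >= 2", call. = FALSE)
  max_interruption <- assert_count(max_interruption, "max_interruption", 0L)
  structure(list(min_repeats = stats::setNames(as.integer(min_repeats), k),
                 max_interruption = max_interruption),
            class = "mining_config")
}

# Is a unit primitive (not a power of a shorter string)?
is_primitive_unit <- function(u) {
  k <- nchar(u)
  if (k <= 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    if (identical(strrep(substr(u, 1L, d), k %/% d), u)) return(FALSE)
  }
  TRUE
}

cyclic_rotations <- function(u) {
  k <- nchar(u)
  vapply(seq_len(k) - 1L, function(i)
    paste0(substr(u, i + 1L, k), substr(u, 1L, i)), character(1))
}

#' Canonical class of a repeat motif
#'
#' The representative of a motif's equivalence class under cyclic rotation
#' and reverse complementation: the lexicographically smallest string among
#' all rotations of the unit and of its reverse complement. Exhaustive
#' enumeration gives 4 classes for dinucleotides, 10 for tri, 33/102/350 for
#' tetra/penta/hexa.
#'
#' @param unit character vector of primitive repeat units (length 2-6, ACGT).
#' @return character vector of class representatives.
#' @export
canonical_class <- function(unit) {
  vapply(unit, function(u) {
    u <- toupper(u)
    k <- nchar(u)
    if (k < 2L || k > 6L || grepl("[^ACGT]", u))
      stop("invalid repeat unit: ", u, call. = FALSE)
    if (!is_primitive_unit(u))
      stop("non-primitive repeat unit: ", u, call. = FALSE)
    min(c(cyclic_rotations(u), cyclic_rotations(revcomp(u))))
  }, character(1), USE.NAMES = FALSE)
}

#' Printed labels for canonical motif classes
#'
#' Published motif tables traditionally label a few trinucleotide classes by
#' a non-minimal representative. This fixed alias table maps the canonical
#' (lexicographically minimal) representative to that printed label so
#' published count tables join cleanly; classes not listed are their own
#' label.
#'
#' @param canonical character vector of canonical class representatives.
#' @return character vector of display labels.
#' @export
motif_label <- function(canonical) {
  aliases <- c(ATC = "ATG", CCG = "GGC", ACT = "AGT")
  out <- canonical
  hit <- canonical %in% names(aliases)
  out[hit] <- aliases[canonical[hit]]
  out
}

# Candidate maximal runs for one unit length in one uppercase sequence.
# Shift-and-match: ok[i] <- s[i] == s[i+k] (FALSE at non-ACGT); a maximal
# TRUE-run of length m starting at i is a maximal tandem region i..i+m+k-1.
.runs_for_k <- function(s, chars, k, min_rep) {
  n <- length(chars)
  if (n < k * min_rep) return(NULL)
  acgt <- chars %in% c("A", "C", "G", "T")
  idx <- seq_len(n - k)
  ok <- chars[idx] == chars[idx + k] & acgt[idx] & acgt[idx + k]
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= k * (min_rep - 1L)
  if (!any(sel)) return(NULL)
  i <- starts[sel]
  m <- r$lengths[sel]
  count <- (m + k) %/% k
  keep <- count >= min_rep
  if (!any(keep)) return(NULL)
  i <- i[keep]; count <- count[keep]
  unit <- substring(s, i, i + k - 1L)
  prim <- vapply(unit, is_primitive_unit, logical(1), USE.NAMES = FALSE)
  if (!any(prim)) return(NULL)
  data.frame(start = i[prim], end = i[prim] + count[prim] * k - 1L,
             unit = unit[prim], unit_length = k,
             repeat_count = count[prim], stringsAsFactors = FALSE)
}

# Resolve same-unit-length overlaps: ascending start, first come first kept.
.resolve_overlaps <- function(runs) {
  if (is.null(runs) || nrow(runs) <= 1L) return(runs)
  runs <- runs[order(runs$start, -runs$end), , drop = FALSE]
  keep <- logical(nrow(runs))
  last_end <- 0L
  for (i in seq_len(nrow(runs))) {
    if (runs$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- runs$end[i]
    }
  }
  runs[keep, , drop = FALSE]
}

.empty_loci <- function() {
  data.frame(contig_id = character(0), ssr_nr = integer(0),
             ssr_type = character(0), unit = character(0),
             canonical = character(0), unit_length = integer(0),
             repeat_count = integer(0), start = integer(0), end = integer(0),
             length_bp = integer(0), motif = character(0),
             stringsAsFactors = FALSE)
}

#' Detect perfect microsatellites
#'
#' Finds all maximal perfect tandem repeats of primitive 2-6 bp units meeting
#' the per-unit-length minimum repeat counts, in ascending start order per
#' contig. Runs separated by at most `cfg$max_interruption` bp (including
#' overlapping runs of different unit lengths) are merged into one compound
#' record (`ssr_type` "c") spanning all of them; the constituent runs are
#' kept in the `children` attribute, keyed by contig id and compound start.
#'
#' @param seqs named character vector of contigs (case-insensitive; only
#'   A/C/G/T positions can be part of a repeat).
#' @param cfg a [mining_config()].
#' @return data.frame with columns contig_id, ssr_nr, ssr_type (p2..p6 or c),
#'   unit, canonical, unit_length, repeat_count (NA for compounds), start,
#'   end, length_bp, motif (MISA-style, e.g. `(AT)7`); attribute `children`
#'   holds the constituent pure runs of every compound record.
#' @export
detect_ssrs <- function(seqs, cfg = mining_config()) {
  assert_contigs(seqs)
  stopifnot(inherits(cfg, "mining_config"))
  res <- vector("list", length(seqs))
  kids <- vector("list", length(seqs))
  for (ci in seq_along(seqs)) {
    s <- toupper(seqs[[ci]])
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    runs <- do.call(rbind, lapply(2:6, function(k)
      .resolve_overlaps(.runs_for_k(s, chars, k, cfg$min_repeats[[as.character(k)]]))))
    if (is.null(runs) || nrow(runs) == 0L) next
    runs <- runs[order(runs$start, runs$end), , drop = FALSE]
    # merge chains of runs within max_interruption bp into compounds
    grp <- integer(nrow(runs))
    g <- 1L
    grp[1L] <- g
    cur_end <- runs$end[1L]
    for (i in seq_len(nrow(runs))[-1L]) {
      gap <- runs$start[i] - cur_end - 1L
      if (gap <= cfg$max_interruption) grp[i] <- g else grp[i] <- (g <- g + 1L)
      cur_end <- max(cur_end, runs$end[i])
    }
    rows <- lapply(split(seq_len(nrow(runs)), grp), function(ix) {
      sub <- runs[ix, , drop = FALSE]
      if (nrow(sub) == 1L) {
        data.frame(contig_id = names(seqs)[ci],
                   ssr_type = paste0("p", sub$unit_length),
                   unit = sub$unit, canonical = canonical_class(sub$unit),
                   unit_length = sub$unit_length,
                   repeat_count = sub$repeat_count,
                   start = sub$start, end = sub$end,
                   length_bp = sub$end - sub$start + 1L,
                   motif = sprintf("(%s)%d", sub$unit, sub$repeat_count),
                   stringsAsFactors = FALSE)
      } else {
        parts <- character(0)
        for (j in seq_len(nrow(sub))) {
          if (j > 1L) {
            gap <- sub$start[j] - sub$end[j - 1L] - 1L
            if (gap > 0L)
              parts <- c(parts, tolower(substr(s, sub$end[j - 1L] + 1L,
                                               sub$start[j] - 1L)))
          }
          parts <- c(parts, sprintf("(%s)%d", sub$unit[j], sub$repeat_count[j]))
        }
        data.frame(contig_id = names(seqs)[ci], ssr_type = "c",
                   unit = NA_character_, canonical = NA_character_,
                   unit_length = NA_integer_, repeat_count = NA_integer_,
                   start = min(sub$start), end = max(sub$end),
                   length_bp = max(sub$end) - min(sub$start) + 1L,
                   motif = paste(parts, collapse = ""),
                   stringsAsFactors = FALSE)
      }
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$start), , drop = FALSE]
    tab$ssr_nr <- seq_len(nrow(tab))
    res[[ci]] <- tab
    comp <- which(grp %in% grp[duplicated(grp)])
    if (length(comp)) {
      ch <- runs[comp, , drop = FALSE]
      ch$contig_id <- names(seqs)[ci]
      ch$canonical <- canonical_class(ch$unit)
      ch$compound_start <- vapply(grp[comp], function(g2)
        min(runs$start[grp == g2]), integer(1))
      kids[[ci]] <- ch
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- .empty_loci()
  out <- out[, c("contig_id", "ssr_nr", "ssr_type", "unit", "canonical",
                 "unit_length", "repeat_count", "start", "end", "length_bp",
                 "motif")]
  rownames(out) <- NULL
  children <- do.call(rbind, kids)
  if (!is.null(children)) rownames(children) <- NULL
  attr(out, "children") <- children
  out
}

#' Decompose loci into pure runs
#'
#' Pure loci pass through; compound records are replaced by their constituent
#' runs (used for repeat-length spectra and polymorphism thresholds).
#'
#' @param loci result of [detect_ssrs()].
#' @return data.frame of pure runs with columns contig_id, unit, canonical,
#'   unit_length, repeat_count, start, end.
#' @export
pure_runs <- function(loci) {
  pure <- loci[loci$ssr_type != "c",
               c("contig_id", "unit", "canonical", "unit_length",
                 "repeat_count", "start", "end")]
  ch <- attr(loci, "children")
  if (!is.null(ch) && nrow(ch))
    pure <- rbind(pure, ch[, c("contig_id", "unit", "canonical",
                               "unit_length", "repeat_count", "start", "end")])
  pure <- pure[order(pure$contig_id, pure$start), ]
  rownames(pure) <- NULL
  pure
}

#' SSR frequency and density
#'
#' Frequency is the percentage of contigs containing at least one SSR;
#' density is the number of SSR records per 10 kbp of contig sequence.
#'
#' @param seqs named character vector of contigs.
#' @param loci result of [detect_ssrs()] over `seqs`.
#' @return list(frequency, density).
#' @export
ssr_frequency_density <- function(seqs, loci) {
  if (length(seqs) == 0L) stop("empty contig collection", call. = FALSE)
  if (!all(loci$contig_id %in% names(seqs)))
    stop("loci reference contigs absent from the collection", call. = FALSE)
  list(frequency = ssr_frequency_from_counts(length(unique(loci$contig_id)),
                                             length(seqs)),
       density = ssr_density_from_counts(nrow(loci), sum(nchar(seqs))))
}

#' @rdname ssr_frequency_density
#' @param n_ssr_contigs number of contigs containing at least one SSR.
#' @param n_contigs total number of contigs.
#' @export
ssr_frequency_from_counts <- function(n_ssr_contigs, n_contigs) {
  if (n_contigs <= 0L) stop("empty contig collection", call. = FALSE)
  100 * n_ssr_contigs / n_contigs
}

#' @rdname ssr_frequency_density
#' @param n_loci number of SSR records.
#' @param total_bp total contig length in bp.
#' @export
ssr_density_from_counts <- function(n_loci, total_bp) {
  if (total_bp <= 0L) stop("no sequence", call. = FALSE)
  n_loci / (total_bp / 10000)
}

#' Repeat-length spectrum
#'
#' Cross-tabulation of pure runs by canonical class and repeat count,
#' complete with zero cells over the observed repeat-count range. Compound
#' records are decomposed into their constituent runs first.
#'
#' @param loci result of [detect_ssrs()].
#' @return data.frame with columns canonical, repeat_count, n (zero rows for
#'   empty input).
#' @export
repeat_length_spectrum <- function(loci) {
  pure <- pure_runs(loci)
  if (nrow(pure) == 0L)
    return(data.frame(canonical = character(0), repeat_count = integer(0),
                      n = integer(0), stringsAsFactors = FALSE))
  rng <- seq(min(pure$repeat_count), max(pure$repeat_count))
  tab <- table(factor(pure$canonical),
               factor(pure$repeat_count, levels = rng))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("canonical", "repeat_count", "n")
  out$repeat_count <- as.integer(out$repeat_count)
  out$n <- as.integer(out$n)
  out[order(out$canonical, out$repeat_count), ]
}

#' Write SSR loci as a MISA-compatible TSV
#'
#' Columns: ID, SSR nr., SSR type, SSR, size, start, end.
#'
#' @param loci result of [detect_ssrs()].
#' @param path output path.
#' @export
write_misa <- function(loci, path) {
  out <- data.frame(ID = loci$contig_id, `SSR nr.` = loci$ssr_nr,
                    `SSR type` = loci$ssr_type, SSR = loci$motif,
                    size = loci$length_bp, start = loci$start,
                    end = loci$end, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write SSR loci as GFF3
#'
#' Feature type `microsatellite`, 1-based inclusive coordinates.
#'
#' @param loci result of [detect_ssrs()].
#' @param path output path.
#' @export
write_ssr_gff3 <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(loci)) {
    attrs <- sprintf("ID=%s.ssr%d;motif=%s;ssr_type=%s",
                     loci$contig_id, loci$ssr_nr, loci$motif, loci$ssr_type)
    writeLines(paste(loci$contig_id, "estssr", "microsatellite", loci$start,
                     loci$end, ".", "+", ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}
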