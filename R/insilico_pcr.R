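# In-silico PCR and the CMiB marker-selection core.
#
# Amplicons are predicted ipcress-style: a primer binds where it matches the
# template with at most `max_mismatch` substitutions and an exactly matching
# 3'-terminal base; binding sites of a productive pair may not overlap, and
# products are capped at a configurable ceiling. "Unique product" is
# enforced across the entire template collection, so repetitive domains
# within a single sequence also disqualify a pair.

#' Predict amplification products of a primer pair
#'
#' Reports every product on either strand where the forward primer matches
#' with at most `max_mismatch` substitutions (3'-terminal base exact) and
#' the reverse primer's reverse complement matches downstream under the same
#' rule, with non-overlapping footprints and product length at most
#' `max_product`.
#'
#' @param forward_seq,reverse_seq primer sequences, 5' to 3'.
#' @param templates named character vector of template sequences.
#' @param max_mismatch allowed substitutions per primer (default 0, the
#'   ipcress default).
#' @param max_product product-length ceiling in bp (default 5000).
#' @return data.frame (template_id, start, end, length_bp, strand,
#'   mismatches_forward, mismatches_reverse).
#' @export
find_amplicons <- function(forward_seq, reverse_seq, templates,
                           max_mismatch = 0L, max_product = 5000L) {
  assert_contigs(templates, "templates")
  if (length(templates) == 0L) stop("templates non-empty required", call. = FALSE)
  max_mismatch <- assert_count(max_mismatch, "max_mismatch", 0L)
  fwd <- toupper(forward_seq); rev_ <- toupper(reverse_seq)
  if (grepl("[^ACGT]", fwd) || grepl("[^ACGT]", rev_))
    stop("primers must be ACGT only", call. = FALSE)
  lf <- nchar(fwd); lr <- nchar(rev_)

  # binding sites of `pat` on `subj`, with the base at `anchor` ("first" or
  # "last") required to match exactly
  sites <- function(pat, subj, anchor) {
    m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch,
                                  with.indels = FALSE)
    st <- Biostrings::start(m)
    if (length(st) == 0L)
      return(data.frame(start = integer(0), mism = integer(0)))
    lp <- nchar(pat)
    anchor_pos <- if (anchor == "last") st + lp - 1L else st
    anchor_base <- if (anchor == "last") substr(pat, lp, lp) else substr(pat, 1L, 1L)
    sub_chars <- as.character(Biostrings::extractAt(
      subj, IRanges::IRanges(anchor_pos, anchor_pos)))
    keep <- sub_chars == anchor_base
    st <- st[keep]
    if (length(st) == 0L)
      return(data.frame(start = integer(0), mism = integer(0)))
    mm <- vapply(st, function(s0) {
      seg <- as.character(Biostrings::subseq(subj, s0, s0 + lp - 1L))
      sum(strsplit(seg, "")[[1L]] != strsplit(pat, "")[[1L]])
    }, integer(1))
    data.frame(start = st, mism = mm)
  }

  out <- list()
  for (ti in seq_along(templates)) {
    subj <- Biostrings::DNAString(toupper(templates[[ti]]))
    # plus-strand product: forward site upstream, revcomp(reverse) downstream
    fsites <- sites(fwd, subj, "last")
    rsites <- sites(revcomp(rev_), subj, "first")
    if (nrow(fsites) && nrow(rsites)) {
      for (i in seq_len(nrow(fsites))) {
        j <- which(rsites$start >= fsites$start[i] + lf &
                     rsites$start + lr - 1L - fsites$start[i] + 1L <= max_product)
        for (jj in j)
          out[[length(out) + 1L]] <- data.frame(
            template_id = names(templates)[ti], start = fsites$start[i],
            end = rsites$start[jj] + lr - 1L,
            length_bp = rsites$start[jj] + lr - fsites$start[i],
            strand = "+", mismatches_forward = fsites$mism[i],
            mismatches_reverse = rsites$mism[jj], stringsAsFactors = FALSE)
      }
    }
    # minus-strand product: reverse primer matches the plus strand upstream,
    # revcomp(forward) downstream
    f2 <- sites(revcomp(fwd), subj, "first")
    r2 <- sites(rev_, subj, "last")
    if (nrow(f2) && nrow(r2)) {
      for (i in seq_len(nrow(r2))) {
        j <- which(f2$start >= r2$start[i] + lr &
                     f2$start + lf - 1L - r2$start[i] + 1L <= max_product)
        for (jj in j)
          out[[length(out) + 1L]] <- data.frame(
            template_id = names(templates)[ti], start = r2$start[i],
            end = f2$start[jj] + lf - 1L,
            length_bp = f2$start[jj] + lf - r2$start[i],
            strand = "-", mismatches_forward = f2$mism[jj],
            mismatches_reverse = r2$mism[i], stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length_bp = integer(0),
                      strand = character(0), mismatches_forward = integer(0),
                      mismatches_reverse = integer(0), stringsAsFactors = FALSE)
  res[order(res$template_id, res$start, res$end, res$strand), , drop = FALSE]
}

#' Triage candidates by product count
#'
#' Zero products anywhere gives `no_product`, two or more (including within
#' one template) `multi_product`, exactly one `unique`; a unique product
#' longer than `max_product_report` becomes `oversize`.
#'
#' @param cands candidate table with a `candidate_id` column.
#' @param amplicons data.frame of amplicons carrying `candidate_id`.
#' @param max_product_report sizing ceiling in bp (default 600).
#' @return `cands` with an updated `status` column.
#' @export
triage_unique <- function(cands, amplicons, max_product_report = 600L) {
  n_amp <- table(amplicons$candidate_id)
  cnt <- as.integer(n_amp[cands$candidate_id])
  cnt[is.na(cnt)] <- 0L
  status <- ifelse(cnt == 0L, "no_product",
                   ifelse(cnt >= 2L, "multi_product", "unique"))
  if (any(status == "unique")) {
    one <- amplicons[amplicons$candidate_id %in%
                       cands$candidate_id[status == "unique"], ]
    big <- one$candidate_id[one$length_bp > max_product_report]
    status[cands$candidate_id %in% big] <- "oversize"
  }
  cands$status <- status
  cands$n_amplicons <- cnt
  cands
}

#' Select one marker per amplicon cluster
#'
#' Amplicon sequences of unique candidates are clustered by single linkage
#' (identity 0.90, coverage 0.5 by default); within each cluster the
#' candidate with the shortest expected product gains status `selected`
#' (ties by smallest template id, then forward start).
#'
#' @param cands candidate table (all rows with status "unique" take part).
#' @param amplicons amplicon table with `candidate_id`.
#' @param templates named character vector the amplicons refer to.
#' @param p a [cluster_params()] for the amplicon clustering.
#' @return `cands` with `status` and `cluster_id` updated.
#' @export
select_markers <- function(cands, amplicons, templates,
                           p = cluster_params(identity_threshold = 0.90,
                                              coverage_threshold = 0.5)) {
  uniq <- cands$candidate_id[cands$status == "unique"]
  if (!("cluster_id" %in% names(cands))) cands$cluster_id <- NA_character_
  if (length(uniq) == 0L) return(cands)
  amp <- amplicons[match(uniq, amplicons$candidate_id), ]
  seqs <- stats::setNames(
    substr(templates[amp$template_id], amp$start, amp$end), uniq)
  cl <- single_linkage_cluster(seqs, p)
  cands$cluster_id[match(cl$member_id, cands$candidate_id)] <- cl$representative_id
  for (g in unique(cl$representative_id)) {
    members <- cl$member_id[cl$representative_id == g]
    sub <- cands[cands$candidate_id %in% members, ]
    sub <- sub[order(sub$expected_product_bp, sub$template_id,
                     sub$forward_start), ]
    cands$status[cands$candidate_id == sub$candidate_id[1L]] <- "selected"
  }
  cands
}

#' Exclude candidates matching known markers
#'
#' A candidate whose source sequence reaches a local-alignment score above
#' `score_threshold` against any known marker sequence (either strand,
#' +1/-3 with gap open 5 and extend 2) is relabeled `known_marker`.
#'
#' @param cands candidate table; rows with status "unique" or "selected"
#'   are screened.
#' @param templates named character vector holding each candidate's source
#'   sequence (keyed by `template_id`).
#' @param known named character vector of known marker sequences (empty or
#'   NULL means no exclusions).
#' @param score_threshold HSP score above which a candidate is excluded
#'   (default 50).
#' @param p a [cluster_params()] carrying the alignment scoring.
#' @return `cands` with `status` updated.
#' @export
exclude_known <- function(cands, templates, known, score_threshold = 50,
                          p = cluster_params()) {
  if (is.null(known) || length(known) == 0L) return(cands)
  screen <- which(cands$status %in% c("unique", "selected"))
  for (i in screen) {
    src <- templates[[cands$template_id[i]]]
    for (kseq in known) {
      if (local_hit(src, kseq, p)$score > score_threshold) {
        cands$status[i] <- "known_marker"
        break
      }
    }
  }
  cands
}

#' Default CMiB configuration
#'
#' @param mining a [mining_config()]; the marker-design convention merges
#'   runs within 100 bp.
#' @param cluster a [cluster_params()] for input clustering (identity 0.8).
#' @param select a [cluster_params()] for amplicon clustering (identity
#'   0.9, coverage 0.5).
#' @param design a [design_constraints()].
#' @param max_mismatch in-silico PCR mismatch allowance (default 0).
#' @param max_product in-silico PCR product ceiling (default 5000).
#' @param known_score_threshold HSP score gate for known-marker exclusion.
#' @return list of class `cmib_config`.
#' @export
cmib_config <- function(mining = mining_config(max_interruption = 100L),
                        cluster = cluster_params(identity_threshold = 0.80),
                        select = cluster_params(identity_threshold = 0.90,
                                                coverage_threshold = 0.5),
                        design = design_constraints(),
                        max_mismatch = 0L, max_product = 5000L,
                        known_score_threshold = 50) {
  structure(list(mining = mining, cluster = cluster, select = select,
                 design = design, max_mismatch = max_mismatch,
                 max_product = max_product,
                 known_score_threshold = known_score_threshold),
            class = "cmib_config")
}

#' Run the CMiB marker-design pipeline
#'
#' Stages: (1) keep SSR-containing sequences; (2) greedy clustering at
#' identity 0.8, keeping the longest sequence of each cluster; (3) primer
#' design per SSR locus (best-ranked pair); (4) in-silico PCR of every pair
#' against all retained unique sequences and triage to single products;
#' (5) amplicon clustering with shortest-product selection; (6) known-marker
#' exclusion.
#'
#' @param seqs named character vector of input sequences.
#' @param known optional named character vector of known marker sequences.
#' @param cfg a [cmib_config()].
#' @return list with elements `candidates` (full provenance table: one row
#'   per designed pair with terminal status), `amplicons`, `representatives`
#'   (ids retained after clustering), and `selected` (subset of candidates
#'   with status "selected").
#' @export
run_cmib <- function(seqs, known = NULL, cfg = cmib_config()) {
  assert_contigs(seqs)
  loci <- detect_ssrs(seqs, cfg$mining)
  with_ssr <- unique(loci$contig_id)
  if (length(with_ssr) == 0L)
    stop("cmib stage 1 (mining): no SSR-containing sequence", call. = FALSE)
  ssr_seqs <- seqs[with_ssr]
  cl <- greedy_cluster(ssr_seqs, cfg$cluster)
  reps <- unique(cl$representative_id)
  rep_seqs <- ssr_seqs[reps]
  rep_loci <- loci[loci$contig_id %in% reps, , drop = FALSE]

  cand_rows <- list()
  for (i in seq_len(nrow(rep_loci))) {
    tid <- rep_loci$contig_id[i]
    pairs <- design_primers(rep_seqs[[tid]],
                            list(start = rep_loci$start[i],
                                 end = rep_loci$end[i]), cfg$design)
    cand_id <- sprintf("%s.ssr%d", tid, rep_loci$ssr_nr[i])
    if (nrow(pairs) == 0L) {
      cand_rows[[length(cand_rows) + 1L]] <- data.frame(
        candidate_id = cand_id, template_id = tid,
        locus_start = rep_loci$start[i], locus_end = rep_loci$end[i],
        motif = rep_loci$motif[i], forward_seq = NA_character_,
        reverse_seq = NA_character_, forward_start = NA_integer_,
        reverse_end = NA_integer_, tm_forward = NA_real_,
        tm_reverse = NA_real_, expected_product_bp = NA_integer_,
        status = "no_primer", reason = attr(pairs, "reason") %||% "",
        stringsAsFactors = FALSE)
    } else {
      best <- pairs[1L, ]
      cand_rows[[length(cand_rows) + 1L]] <- data.frame(
        candidate_id = cand_id, template_id = tid,
        locus_start = rep_loci$start[i], locus_end = rep_loci$end[i],
        motif = rep_loci$motif[i], forward_seq = best$forward_seq,
        reverse_seq = best$reverse_seq, forward_start = best$forward_start,
        reverse_end = best$reverse_end, tm_forward = best$tm_forward,
        tm_reverse = best$tm_reverse,
        expected_product_bp = best$product_bp, status = "designed",
        reason = "", stringsAsFactors = FALSE)
    }
  }
  cands <- do.call(rbind, cand_rows)
  if (is.null(cands))
    stop("cmib stage 3 (design): no candidate loci", call. = FALSE)

  amp_rows <- list()
  for (i in which(cands$status == "designed")) {
    amp <- find_amplicons(cands$forward_seq[i], cands$reverse_seq[i],
                          rep_seqs, cfg$max_mismatch, cfg$max_product)
    if (nrow(amp)) {
      amp$candidate_id <- cands$candidate_id[i]
      amp_rows[[length(amp_rows) + 1L]] <- amp
    }
  }
  amplicons <- do.call(rbind, amp_rows)
  if (is.null(amplicons))
    amplicons <- data.frame(template_id = character(0), start = integer(0),
                            end = integer(0), length_bp = integer(0),
                            strand = character(0),
                            mismatches_forward = integer(0),
                            mismatches_reverse = integer(0),
                            candidate_id = character(0),
                            stringsAsFactors = FALSE)
  designed <- cands$status == "designed"
  cands$n_amplicons <- 0L
  if (any(designed)) {
    tr <- triage_unique(cands[designed, , drop = FALSE], amplicons,
                        cfg$design$max_product_report)
    cands$status[designed] <- tr$status
    cands$n_amplicons[designed] <- tr$n_amplicons
  }
  cands <- select_markers(cands, amplicons, rep_seqs, cfg$select)
  cands <- exclude_known(cands, rep_seqs, known,
                         cfg$known_score_threshold, cfg$select)
  rownames(cands) <- NULL
  list(candidates = cands, amplicons = amplicons, representatives = reps,
       selected = cands[cands$status == "selected", , drop = FALSE])
}

#' Write the CMiB provenance table
#'
#' @param result list from [run_cmib()].
#' @param path output path.
#' @export
write_provenance <- function(result, path) {
  utils::write.table(result$candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
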