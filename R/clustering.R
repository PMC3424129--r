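# Greedy identity-based sequence clustering.
#
# Two flavors: representative-based input clustering (CD-HIT-EST style,
# identity of the shorter sequence against the best window of the longer)
# and single-linkage clustering of amplicons (BlastCLUST style, local
# alignment with an identity and a coverage gate). Identity is defined by
# dynamic-programming alignment, not by a k-mer heuristic, so results are
# reproducible; the optional word-size prefilter is purely an optimization
# and the test suite asserts it never changes the outcome.

#' Clustering parameters
#'
#' @param identity_threshold fraction in (0, 1]; default 0.80 for input
#'   clustering (use 0.90 for amplicon clustering).
#' @param coverage_threshold fraction of a sequence a local hit must cover
#'   for single-linkage clustering (either sequence may satisfy it);
#'   ignored by [greedy_cluster()].
#' @param both_strands also compare reverse complements (default TRUE).
#' @param word_size k-mer size of the optional prefilter, 3-12.
#' @param match,mismatch,gap_open,gap_extend alignment scoring (classic
#'   nucleotide BLAST defaults +1/-3/-5/-2; gap penalties given as positive
#'   costs).
#' @param use_prefilter skip alignment for pairs sharing no word_size-mer
#'   (default FALSE; an optimization that must not change results).
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(identity_threshold = 0.80,
                           coverage_threshold = 0.5,
                           both_strands = TRUE, word_size = 4L,
                           match = 1, mismatch = -3,
                           gap_open = 5, gap_extend = 2,
                           use_prefilter = FALSE) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            coverage_threshold > 0, coverage_threshold <= 1,
            word_size >= 3L, word_size <= 12L)
  structure(list(identity_threshold = identity_threshold,
                 coverage_threshold = coverage_threshold,
                 both_strands = isTRUE(both_strands),
                 word_size = as.integer(word_size),
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 use_prefilter = isTRUE(use_prefilter)),
            class = "cluster_params")
}

.submat <- function(p) Biostrings::nucleotideSubstitutionMatrix(
  match = p$match, mismatch = p$mismatch, baseOnly = FALSE)

.kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

.share_kmer <- function(a, b, p) {
  ka <- .kmer_set(toupper(a), p$word_size)
  kb <- .kmer_set(toupper(b), p$word_size)
  if (p$both_strands) kb <- unique(c(kb, .kmer_set(revcomp(toupper(b)), p$word_size)))
  any(ka %in% kb)
}

#' Global identity of the shorter sequence over the longer
#'
#' Aligns the shorter sequence globally against the best local window of the
#' longer (semi-global alignment) and returns matches / alignment columns,
#' maximized over strands when `p$both_strands`.
#'
#' @param a,b sequences (single strings).
#' @param p a [cluster_params()].
#' @return identity fraction in \[0, 1\].
#' @export
seq_identity <- function(a, b, p = cluster_params()) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  ids <- Biostrings::pid(Biostrings::pairwiseAlignment(
    a, b, type = "global-local", substitutionMatrix = .submat(p),
    gapOpening = p$gap_open, gapExtension = p$gap_extend), type = "PID1") / 100
  if (p$both_strands) {
    ids2 <- Biostrings::pid(Biostrings::pairwiseAlignment(
      revcomp(a), b, type = "global-local", substitutionMatrix = .submat(p),
      gapOpening = p$gap_open, gapExtension = p$gap_extend), type = "PID1") / 100
    ids <- max(ids, ids2)
  }
  ids
}

#' Best local alignment between two sequences
#'
#' @inheritParams seq_identity
#' @return list(score, identity, cov_a, cov_b): identity over alignment
#'   columns and coverage of each sequence by the aligned region, maximized
#'   over strands by score.
#' @export
local_hit <- function(a, b, p = cluster_params()) {
  a <- toupper(a); b <- toupper(b)
  one <- function(x) {
    al <- Biostrings::pairwiseAlignment(
      x, b, type = "local", substitutionMatrix = .submat(p),
      gapOpening = p$gap_open, gapExtension = p$gap_extend)
    list(score = Biostrings::score(al),
         identity = Biostrings::pid(al, type = "PID1") / 100,
         cov_a = Biostrings::width(Biostrings::pattern(al)) / nchar(x),
         cov_b = Biostrings::width(Biostrings::subject(al)) / nchar(b))
  }
  best <- one(a)
  if (p$both_strands) {
    alt <- one(revcomp(a))
    if (alt$score > best$score) best <- alt
  }
  best
}

.cluster_df <- function(cluster_id, representative_id, member_id) {
  data.frame(cluster_id = cluster_id, representative_id = representative_id,
             member_id = member_id, stringsAsFactors = FALSE)
}

#' Greedy representative-based clustering (CD-HIT-EST style)
#'
#' Sequences are processed in descending length order (ties by id); each
#' joins the first cluster whose representative reaches the identity
#' threshold over the shorter sequence's length, else founds a new cluster.
#' Representatives are therefore the longest member of each cluster, and the
#' outcome does not depend on input order.
#'
#' @param seqs named character vector.
#' @param p a [cluster_params()] (identity 0.80 by default).
#' @return data.frame (cluster_id, representative_id, member_id), one row
#'   per input sequence.
#' @export
greedy_cluster <- function(seqs, p = cluster_params()) {
  assert_contigs(seqs)
  if (length(seqs) == 0L) stop("empty input", call. = FALSE)
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  seqs <- seqs[ord]
  reps <- integer(0)            # indices of representatives
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      r <- reps[ci]
      if (p$use_prefilter && !.share_kmer(seqs[[i]], seqs[[r]], p)) next
      if (seq_identity(seqs[[i]], seqs[[r]], p) >= p$identity_threshold) {
        assign[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- length(reps)
    }
  }
  .cluster_df(assign, names(seqs)[reps[assign]], names(seqs))
}

#' Single-linkage clustering of amplicon sequences (BlastCLUST style)
#'
#' Two sequences are linked iff a local alignment reaches the identity
#' threshold and covers at least `coverage_threshold` of either of them;
#' clusters are the connected components, labeled (and represented) by
#' their smallest member id.
#'
#' @param seqs named character vector.
#' @param p a [cluster_params()] (use identity 0.90, coverage 0.5 for the
#'   marker-selection stage).
#' @return data.frame (cluster_id, representative_id, member_id).
#' @export
single_linkage_cluster <- function(seqs, p = cluster_params(identity_threshold = 0.90)) {
  assert_contigs(seqs)
  n <- length(seqs)
  if (n == 0L) stop("empty input", call. = FALSE)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (find(i) == find(j)) next
    if (p$use_prefilter && !.share_kmer(seqs[[i]], seqs[[j]], p)) next
    h <- local_hit(seqs[[i]], seqs[[j]], p)
    if (h$identity >= p$identity_threshold &&
        (h$cov_a >= p$coverage_threshold || h$cov_b >= p$coverage_threshold)) {
      parent[find(j)] <- find(i)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  ids <- names(seqs)
  rep_id <- vapply(split(ids, comp), min, character(1))
  comp_label <- rep_id[as.character(comp)]
  # deterministic numbering by smallest member id
  lv <- sort(unique(comp_label))
  .cluster_df(match(comp_label, lv), comp_label, ids)
}
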