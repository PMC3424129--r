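# Independent oracles and small simulation helpers shared by the tests.
# Each oracle is a deliberately different algorithm from the implementation
# it checks.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

mutate_seq <- function(s, rate) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

# trailing-TRUE-run lengths of a logical vector
.trail_true <- function(x) {
  n <- length(x)
  t <- integer(n)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) t[starts[j]:ends[j]] <- ends[j]:starts[j] - starts[j] + 1L
  t
}

.oracle_primitive <- function(u) {
  k <- nchar(u)
  for (d in seq_len(k - 1L)) {
    if (k %% d) next
    if (paste(rep(substr(u, 1L, d), k / d), collapse = "") == u) return(FALSE)
  }
  TRUE
}

# Brute-force SSR enumerator: every (start, unit length) pair, block-equality
# extension, left/right maximality, primitivity, per-length minima, then
# greedy same-unit-length overlap resolution in ascending start order.
# Returns pure runs only (no compound merging).
oracle_pure_runs <- function(seq, min_repeats = c(`2` = 6L, `3` = 5L,
                                                  `4` = 4L, `5` = 3L,
                                                  `6` = 3L)) {
  s <- toupper(seq)
  n <- nchar(s)
  all_rows <- list()
  acgt_ok <- !grepl("[^ACGT]", strsplit(s, "", fixed = TRUE)[[1]])
  for (k in 2:6) {
    minr <- min_repeats[[as.character(k)]]
    if (n < k * minr) next
    np <- n - 2L * k + 1L
    if (np < 1L) next
    blk_eq <- substring(s, 1:np, k:(np + k - 1L)) ==
      substring(s, (k + 1L):(np + k), (2L * k):(np + 2L * k - 1L))
    # unit must be over ACGT; block equality must not bridge non-ACGT
    unit_ok <- vapply(1:(n - k + 1L), function(p) all(acgt_ok[p:(p + k - 1L)]),
                      logical(1))
    blk_eq <- blk_eq & unit_ok[1:np] & unit_ok[(k + 1L):(np + k)]
    # repeat count from each start, per residue class mod k
    count <- integer(n - k + 1L)
    for (r in seq_len(k)) {
      idx <- seq(r, np, by = k)
      if (length(idx) == 0L) {
        count[seq(r, n - k + 1L, by = k)] <- 1L
        next
      }
      t <- .trail_true(blk_eq[idx])
      pos <- seq(r, n - k + 1L, by = k)
      count[pos] <- 1L
      count[idx] <- 1L + t
    }
    cand <- list()
    for (p in seq_len(n - k + 1L)) {
      if (count[p] < minr) next
      u <- substr(s, p, p + k - 1L)
      if (!unit_ok[p] || !.oracle_primitive(u)) next
      # left-maximal: one more unit to the left must not match
      if (p > k && substr(s, p - k, p - 1L) == u) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = p, end = p + count[p] * k - 1L, unit = u,
        unit_length = k, repeat_count = count[p], stringsAsFactors = FALSE)
    }
    cand <- do.call(rbind, cand)
    if (is.null(cand)) next
    cand <- cand[order(cand$start, -cand$end), , drop = FALSE]
    last_end <- 0L
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (cand$start[i] > last_end) {
        keep[i] <- TRUE
        last_end <- cand$end[i]
      }
    }
    all_rows[[length(all_rows) + 1L]] <- cand[keep, , drop = FALSE]
  }
  out <- do.call(rbind, all_rows)
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      unit = character(0), unit_length = integer(0),
                      repeat_count = integer(0), stringsAsFactors = FALSE))
  out <- out[order(out$start, out$unit_length), ]
  rownames(out) <- NULL
  out
}

# mining result of detect_ssrs() reduced to comparable pure runs
impl_pure_runs <- function(seq, cfg = mining_config()) {
  loci <- detect_ssrs(c(q = seq), cfg)
  out <- pure_runs(loci)[, c("start", "end", "unit", "unit_length",
                             "repeat_count")]
  out <- out[order(out$start, out$unit_length), ]
  rownames(out) <- NULL
  out
}

# Position-scan in-silico PCR oracle: mismatch counts at every offset by
# per-column vector comparison, then all site pairs.
oracle_amplicons <- function(forward, reverse, templates, max_mismatch = 0L,
                             max_product = 5000L) {
  scan <- function(pat, tc) {
    L <- nchar(pat)
    n <- length(tc)
    if (n < L) return(integer(0))
    pc <- strsplit(pat, "", fixed = TRUE)[[1]]
    mm <- integer(n - L + 1L)
    for (j in seq_len(L)) mm <- mm + (tc[j:(j + n - L)] != pc[j])
    mm
  }
  rows <- list()
  for (ti in seq_along(templates)) {
    tmpl <- toupper(templates[[ti]])
    tc <- strsplit(tmpl, "", fixed = TRUE)[[1]]
    lf <- nchar(forward); lr <- nchar(reverse)
    fw <- toupper(forward); rv <- toupper(reverse)
    push <- function(start, end, strand, mf, mr) {
      rows[[length(rows) + 1L]] <<- data.frame(
        template_id = names(templates)[ti], start = start, end = end,
        length_bp = end - start + 1L, strand = strand,
        mismatches_forward = mf, mismatches_reverse = mr,
        stringsAsFactors = FALSE)
    }
    # plus strand
    mmf <- scan(fw, tc)
    mmr <- scan(revcomp(rv), tc)
    fs <- which(mmf <= max_mismatch &
                  tc[seq_along(mmf) + lf - 1L] == substr(fw, lf, lf))
    rs <- which(mmr <= max_mismatch &
                  tc[seq_along(mmr)] == substr(revcomp(rv), 1L, 1L))
    for (i in fs) for (j in rs)
      if (j >= i + lf && (j + lr - i) <= max_product)
        push(i, j + lr - 1L, "+", mmf[i], mmr[j])
    # minus strand
    mmf2 <- scan(revcomp(fw), tc)
    mmr2 <- scan(rv, tc)
    f2 <- which(mmf2 <= max_mismatch &
                  tc[seq_along(mmf2)] == substr(revcomp(fw), 1L, 1L))
    r2 <- which(mmr2 <= max_mismatch &
                  tc[seq_along(mmr2) + lr - 1L] == substr(rv, lr, lr))
    for (i in r2) for (j in f2)
      if (j >= i + lr && (j + lf - i) <= max_product)
        push(i, j + lf - 1L, "-", mmf2[j], mmr2[i])
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length_bp = integer(0),
                      strand = character(0), mismatches_forward = integer(0),
                      mismatches_reverse = integer(0),
                      stringsAsFactors = FALSE))
  out <- out[order(out$template_id, out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

# One-sided hypergeometric upper-tail P(X >= a) by direct log-binomial sum.
oracle_hyper_tail <- function(a, b, cc, d) {
  N <- a + b + cc + d
  K <- a + cc           # total with term
  n <- a + b            # subset size
  i <- a:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}
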