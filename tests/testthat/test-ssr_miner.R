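test_that("detect_ssrs applies the per-unit-length minima", {
  hit <- detect_ssrs(c(a = "ATATATATATAT"))
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$unit, "AT")
  expect_identical(hit$repeat_count, 6L)
  expect_identical(c(hit$start, hit$end), c(1L, 12L))
  expect_identical(hit$ssr_type, "p2")

  expect_identical(nrow(detect_ssrs(c(a = "ATATATATAT"))), 0L)

  tri <- detect_ssrs(c(a = "AAGAAGAAGAAGAAG"))
  expect_identical(tri$ssr_type, "p3")
  expect_identical(tri$repeat_count, 5L)
})

test_that("adjacent qualifying runs merge into one compound record", {
  comp <- detect_ssrs(c(a = "ATATATATATATAAGAAGAAGAAGAAG"))
  expect_identical(comp$ssr_type, "c")
  expect_identical(c(comp$start, comp$end), c(1L, 27L))
  expect_identical(comp$motif, "(AT)6(AAG)5")
  kids <- attr(comp, "children")
  expect_identical(nrow(kids), 2L)
  expect_identical(sort(kids$unit), c("AAG", "AT"))
  # with a gap wider than max_interruption the runs stay separate
  gap <- detect_ssrs(c(a = paste0("ATATATATATAT", "GCGGA",
                                  "AAGAAGAAGAAGAAG")))
  expect_identical(gap$ssr_type, c("p2", "p3"))
  # ... but merge under the marker-design interruption setting
  gap2 <- detect_ssrs(c(a = paste0("ATATATATATAT", "GCGGA",
                                   "AAGAAGAAGAAGAAG")),
                      mining_config(max_interruption = 100L))
  expect_identical(gap2$ssr_type, "c")
  expect_identical(gap2$motif, "(AT)6gcgga(AAG)5")
})

test_that("mining equals the brute-force enumerator on random sequences", {
  set.seed(20)
  for (i in 1:50) {
    n <- sample(200:2000, 1)
    s <- random_dna(n, runif(1, 0.3, 0.6))
    if (i %% 2 == 0) {  # spike a repeat to hit the detection path often
      u <- sample(c("AT", "CT", "AAG", "ATCG", "AACGT", "ACGTAG"), 1)
      r <- sample(3:10, 1)
      p <- sample(seq_len(n - nchar(u) * r), 1)
      substr(s, p, p + nchar(u) * r - 1L) <- strrep(u, r)
    }
    expect_equal(impl_pure_runs(s), oracle_pure_runs(s))
  }
})

test_that("runs never span non-ACGT bases and never overlap within a unit length", {
  set.seed(21)
  # an N inside a repeat splits it: neither half reaches the minimum here
  split_run <- impl_pure_runs(paste0(strrep("AT", 4), "N", strrep("AT", 4)))
  expect_identical(nrow(split_run), 0L)
  # ... but long halves are reported separately
  halves <- impl_pure_runs(paste0(strrep("AT", 6), "N", strrep("AT", 6)))
  expect_identical(nrow(halves), 2L)
  expect_identical(halves$start, c(1L, 14L))
  for (i in 1:20) {
    s <- random_dna(1000L)
    u <- sample(c("AT", "AG", "AAG"), 1)
    p0 <- sample(800L, 1L)
    substr(s, p0, p0 + nchar(u) * 7L - 1L) <- strrep(u, 7L)
    p <- sample(900L, 1L)
    substr(s, p, p) <- "N"
    runs <- impl_pure_runs(s)
    if (nrow(runs) == 0L) next
    for (j in seq_len(nrow(runs)))
      expect_false(grepl("N", substr(s, runs$start[j], runs$end[j])))
    for (k in unique(runs$unit_length)) {
      rk <- runs[runs$unit_length == k, ]
      if (nrow(rk) < 2L) next
      rk <- rk[order(rk$start), ]
      expect_true(all(rk$start[-1L] > rk$end[-nrow(rk)]))
    }
  }
})

test_that("mining the reverse complement mirrors loci and classes", {
  set.seed(22)
  for (i in 1:10) {
    s <- random_dna(800L, 0.45)
    u <- sample(c("AT", "AG", "AAG", "ATC"), 1)
    p <- 300L
    substr(s, p, p + nchar(u) * 7L - 1L) <- strrep(u, 7L)
    # clean flanks: phase-shifted partial extension would legitimately move
    # the maximal run by a base or two and break exact mirroring
    pad <- setdiff(c("A", "C", "G", "T"),
                   c(substr(u, 1L, 1L), substr(u, nchar(u), nchar(u))))[1L]
    substr(s, p - 1L, p - 1L) <- pad
    substr(s, p + nchar(u) * 7L, p + nchar(u) * 7L) <- pad
    fwd <- pure_runs(detect_ssrs(c(a = s)))
    rev_ <- pure_runs(detect_ssrs(c(a = revcomp(s))))
    expect_identical(nrow(fwd), nrow(rev_))
    expect_identical(sort(fwd$canonical), sort(rev_$canonical))
    n <- nchar(s)
    mirrored <- data.frame(start = n - rev_$end + 1L, end = n - rev_$start + 1L)
    expect_setequal(paste(fwd$start, fwd$end),
                    paste(mirrored$start, mirrored$end))
  }
})

test_that("canonical_class picks the minimal rotation/revcomp representative", {
  expect_identical(canonical_class(c("TA", "CT")), c("AT", "AG"))
  # hand enumeration: TTC rotations TTC,TCT,CTT; revcomp GAA: GAA,AAG,AGA -> AAG
  expect_identical(canonical_class("TTC"), "AAG")
  # CAT rotations CAT,ATC,TCA; revcomp ATG: ATG,TGA,GAT -> ATC
  expect_identical(canonical_class("CAT"), "ATC")
  expect_identical(motif_label("ATC"), "ATG")
  expect_identical(motif_label(c("CCG", "ACT", "AAG")),
                   c("GGC", "AGT", "AAG"))
  # idempotent and class-consistent
  set.seed(23)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    repeat {
      u <- paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = "")
      ok <- tryCatch({ canonical_class(u); TRUE }, error = function(e) FALSE)
      if (ok) break
    }
    cc <- canonical_class(u)
    expect_identical(canonical_class(cc), cc)
  }
  expect_error(canonical_class("ATAT"), "non-primitive")
  expect_error(canonical_class("AXT"), "invalid")
})

test_that("exhaustive enumeration yields the known class counts", {
  counts <- vapply(2:6, function(k) {
    kmers <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k)))
    prim <- kmers[vapply(kmers, estssr:::is_primitive_unit, logical(1))]
    length(unique(canonical_class(prim)))
  }, integer(1))
  expect_identical(counts, c(4L, 10L, 33L, 102L, 350L))
})

test_that("frequency and density follow their definitions", {
  expect_equal(round_half_up(ssr_frequency_from_counts(3694L, 81284L), 2L),
               4.54)
  seqs <- c(a = random_dna(10000L))
  loci <- data.frame(contig_id = rep("a", 3L))
  fd <- ssr_frequency_density(seqs, loci)
  expect_equal(fd$density, 3)
  expect_equal(fd$frequency, 100)
  # doubling loci doubles density, leaves frequency unchanged
  fd2 <- ssr_frequency_density(seqs, rbind(loci, loci))
  expect_equal(fd2$density, 6)
  expect_equal(fd2$frequency, fd$frequency)
  expect_error(ssr_frequency_density(character(0), loci), "empty")
})

test_that("repeat_length_spectrum matches a planting manifest", {
  seqs <- c(a = paste0(strrep("AT", 6), strrep("C", 30), strrep("AT", 6),
                       strrep("G", 30), strrep("AT", 7)))
  sp <- repeat_length_spectrum(detect_ssrs(seqs))
  expect_identical(sp$n[sp$canonical == "AT" & sp$repeat_count == 6L], 2L)
  expect_identical(sp$n[sp$canonical == "AT" & sp$repeat_count == 7L], 1L)
  expect_identical(nrow(repeat_length_spectrum(detect_ssrs(c(a = "ACGT")))), 0L)
  # compound children contribute to the spectrum
  comp <- detect_ssrs(c(b = "ATATATATATATAAGAAGAAGAAGAAG"))
  sp2 <- repeat_length_spectrum(comp)
  expect_identical(sum(sp2$n), 2L)
})

test_that("MISA-style TSV writer emits the exact column layout", {
  loci <- detect_ssrs(c(a = "ATATATATATAT"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_misa(loci, tsv)
  lines <- readLines(tsv)
  expect_identical(lines[1L], "ID\tSSR nr.\tSSR type\tSSR\tsize\tstart\tend")
  expect_identical(lines[2L], "a\t1\tp2\t(AT)6\t12\t1\t12")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_ssr_gff3(loci, gff)
  g <- readLines(gff)
  expect_identical(g[1L], "##gff-version 3")
  expect_match(g[2L], "\tmicrosatellite\t1\t12\t")
})
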