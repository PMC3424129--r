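test_that("summarize_by_location reproduces the packaged survey shares", {
  tab <- summarize_by_location(table2_fixture())
  tot <- summary_totals(tab)
  expect_identical(tot$count[tot$group == "grand"], 4059L)
  expect_identical(tot$count[tot$group == "pure"], 4003L)
  expect_identical(tot$count[tot$group == "di"], 655L)
  expect_identical(tot$count[tot$group == "tri"], 1319L)
  expect_identical(tot$count[tot$group == "compound"], 56L)
  expect_equal(summary_percent(tab, "AT"), 46.3)                  # 303/655
  expect_equal(summary_percent(tab, "AAG"), 25.9)                 # 342/1319
  expect_equal(summary_percent(tab, "tri", "coding"), 72.8)       # 960/1319
  expect_equal(summary_percent(tab, "hexa", "coding"), 64.3)      # 703/1094
  expect_equal(summary_percent(tab, "di", "coding"), 42.1)        # 276/655
  expect_equal(summary_percent(tab, "AT", "three_prime_utr"), 23.5)
  expect_equal(summary_percent(tab, "AG", "coding"), 23.7)
  expect_equal(summary_percent(tab, "AT", "five_prime_utr"), 10.7)
  expect_equal(summary_percent(tab, "AT", denom = "pure"), 7.6)   # 303/4003
})

test_that("summarize_by_location works from raw classified loci", {
  loci <- data.frame(ssr_type = c("p2", "p2", "p3", "p6", "c"),
                     unit_length = c(2L, 2L, 3L, 6L, NA),
                     canonical = c("AT", "AT", "AAG", "AACCGT", NA),
                     location = c("coding", "three_prime_utr", "coding",
                                  "no_annotation", "five_prime_utr"),
                     stringsAsFactors = FALSE)
  tab <- summarize_by_location(loci)
  expect_identical(sum(tab$counts), 5L)
  expect_identical(unname(tab$counts["AT", "coding"]), 1L)
  # no_annotation folds into undetermined for reporting
  expect_identical(unname(tab$counts["hexa", "undetermined"]), 1L)
  single <- summarize_by_location(loci[1L, ])
  expect_identical(sum(single$counts), 1L)
  expect_equal(summary_percent(single, "AT", "coding", "grand"), 100)
})

test_that("fit_glm recovers simulated truths and flags degeneracies", {
  truth <- default_glm_truth()
  obs <- generate_marker_outcomes(2000L, truth, seed = 71L)
  fb <- fit_glm(obs, "binomial_logit", "success",
                c("pipeline", "location", "tm_sum", "product_size"),
                ref_levels = list(pipeline = "CMiB", location = "coding"))
  expect_true(fb$converged)
  est <- fb$terms[fb$terms$term == "product_size", ]
  expect_lt(abs(est$estimate - truth$binomial[["product_size"]]),
            3 * est$std_error)
  expect_equal(fb$terms$z, fb$terms$estimate / fb$terms$std_error)
  # reference-level coding: the pipeline term is the read2Marker contrast
  expect_true("pipelineread2Marker" %in% fb$terms$term)

  fp <- fit_glm(obs, "poisson_log", "na",
                c("pipeline", "location", "repeat_count", "unit_length"),
                ref_levels = list(pipeline = "CMiB", location = "coding"))
  estp <- fp$terms[fp$terms$term == "repeat_count", ]
  expect_lt(abs(estp$estimate - truth$poisson[["repeat_count"]]),
            3 * estp$std_error)

  degen <- obs
  degen$success <- 1L
  degen$success[1L] <- 0L
  degen$flag <- rep(c(0L, 1L), 1000L)
  degen$success[degen$flag == 1L] <- 1L
  degen$success[degen$flag == 0L] <- 0L
  expect_warning(fs <- fit_glm(degen, "binomial_logit", "success", "flag"),
                 "separation")
  expect_true(fs$separation)
  expect_error(fit_glm(obs, "binomial_logit", "success", "constant_col"),
               "covariates")
  obs$k <- 1L
  expect_error(fit_glm(obs, "binomial_logit", "success", "k"), "constant")
})

test_that("diversity statistics match their closed forms", {
  mono <- diversity_stats(rep("a", 10L), rep("a", 10L))
  expect_identical(mono[c("Na", "Ho", "He", "PIC")],
                   list(Na = 1L, Ho = 0, He = 0, PIC = 0))
  # two alleles at p = q = 0.5: He = 0.5, PIC = 1 - 0.5 - 2(0.25)(0.25)
  bi <- diversity_stats(c("a", "a", "b", "b"), c("b", "b", "a", "a"))
  expect_equal(bi$He, 0.5)
  expect_equal(bi$PIC, 0.375)
  expect_equal(bi$Ho, 1)
  # missing calls are excluded, order is irrelevant, PIC <= He always
  set.seed(72)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    a1 <- sample(letters[1:4], n, TRUE)
    a2 <- sample(letters[1:4], n, TRUE)
    a1[sample(n, 2L)] <- NA
    d <- diversity_stats(a1, a2)
    perm <- sample(n)
    expect_equal(diversity_stats(a1[perm], a2[perm]), d)
    expect_lte(d$PIC, d$He + 1e-12)
    expect_identical(d$N, sum(!is.na(a1) & !is.na(a2)))
    p <- table(c(a1[!is.na(a1) & !is.na(a2)], a2[!is.na(a1) & !is.na(a2)]))
    p <- p / sum(p)
    expect_equal(d$He, 1 - sum(p^2))
  }
  expect_error(diversity_stats(NA, NA), "missing")
  expect_equal(diversity_stats(c("a", NA), c("a", "b"), unbiased = TRUE)$He, 0)
})

test_that("enrichment p-values equal the hypergeometric tail oracle", {
  set.seed(73)
  # identical distribution in subset and background: p ~ 1
  ann <- data.frame(contig_id = paste0("c", 1:100),
                    term = rep(c("GO:1", "GO:2"), 50L),
                    stringsAsFactors = FALSE)
  res <- enrich_go(ann, paste0("c", 1:50))
  expect_true(all(res$p > 0.4))
  # random 2x2 tables against the direct tail sum
  for (i in 1:25) {
    a <- sample(0:12, 1); b <- sample(5:60, 1)
    cc <- sample(0:30, 1); d <- sample(20:300, 1)
    ids <- paste0("g", seq_len(a + b + cc + d))
    sub <- ids[seq_len(a + b)]
    withterm <- c(ids[seq_len(a)], ids[a + b + seq_len(cc)])
    ann2 <- data.frame(contig_id = ids, term = "T0",
                       stringsAsFactors = FALSE)
    ann2$term[ann2$contig_id %in% withterm] <- "T1"
    if (length(unique(ann2$term)) < 2L) next
    res2 <- enrich_go(ann2, sub)
    got <- res2$p[res2$term == "T1"]
    expect_equal(got, oracle_hyper_tail(a, b, cc, d), tolerance = 1e-9)
    expect_true(all(res2$q >= res2$p - 1e-12))
  }
  expect_error(enrich_go(ann, character(0)), "empty subset")
})

test_that("a planted enriched term ranks first by q", {
  set.seed(74)
  n <- 500L
  ids <- paste0("c", seq_len(n))
  sub <- ids[1:100]
  rows <- list()
  for (tm in paste0("GO:", 1:10)) {
    base_rate <- runif(1, 0.05, 0.15)
    rate <- rep(base_rate, n)
    if (tm == "GO:1") rate[1:100] <- base_rate * 3
    hit <- ids[runif(n) < rate]
    if (length(hit))
      rows[[length(rows) + 1L]] <- data.frame(contig_id = hit, term = tm,
                                              stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  ann <- rbind(ann, data.frame(contig_id = ids, term = "GO:base"))
  res <- enrich_go(ann, sub)
  expect_identical(res$term[1L], "GO:1")
  # q monotone in p
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
})

test_that("welch_t matches the textbook formula", {
  same <- welch_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  got <- welch_t(a, b)
  se <- sqrt(var(a) / 5 + var(b) / 5)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  expect_equal(got$t, t_hand)
  expect_equal(got$df, df_hand)
  expect_equal(got$p, 2 * pt(-abs(t_hand), df_hand))
  # p decreases monotonically with the shift
  set.seed(75)
  x <- rnorm(50)
  ps <- vapply(c(0.2, 0.6, 1.2, 2.4), function(sh)
    welch_t(x, x + sh)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(welch_t(c(1, 1), c(1, 1)), "zero variance")
})

test_that("correlations match direct formula evaluation", {
  x <- c(2, 5, 1, 8, 9, 3, 7, 4)
  y <- c(1, 4, 2, 9, 8, 2, 6, 5)
  got <- rank_and_linear_correlation(x, y)
  expect_equal(got$pearson_r,
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  rx <- rank(x); ry <- rank(y)
  expect_equal(got$spearman_r,
               sum((rx - mean(rx)) * (ry - mean(ry))) /
                 sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2)))
  ident <- rank_and_linear_correlation(x, x)
  expect_equal(ident$spearman_r, 1)
  expect_equal(ident$pearson_r, 1)
  mono <- rank_and_linear_correlation(1:8, (1:8)^3)
  expect_equal(mono$spearman_r, 1)
  expect_warning(flat <- rank_and_linear_correlation(rep(1, 5), 1:5),
                 "constant")
  expect_true(is.na(flat$pearson_r))
})

test_that("polymorphism_forecast applies the calibrated thresholds", {
  expect_identical(as.character(polymorphism_forecast(2L, 9L)), "always")
  expect_identical(as.character(polymorphism_forecast(c(2, 2, 2), c(9, 6, 5))),
                   c("always", "possibly", "unlikely"))
  expect_identical(as.character(polymorphism_forecast(c(3, 3, 3), c(10, 4, 3))),
                   c("always", "possibly", "unlikely"))
  tetra <- polymorphism_forecast(4L, 12L)
  expect_identical(as.character(tetra), "possibly")
  expect_true(attr(tetra, "uncalibrated"))
})
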