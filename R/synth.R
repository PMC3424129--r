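# Synthetic inputs with known ground truth, plus the packaged motif-by-
# location count fixture. Every generator is a pure function of its
# parameters and seed: the caller's RNG state is saved and restored.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# scalar-safe draw from an integer range (sample() would misread 1-vectors)
sample1 <- function(v) v[sample.int(length(v), 1L)]

.random_dna <- function(len, gc) {
  paste(sample(c("A", "T", "G", "C"), len, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Generate contigs with planted SSRs and CDS intervals
#'
#' Background bases are drawn at the target GC; SSRs are planted at
#' recorded positions and each contig is accepted only when mining it back
#' (under `cfg`) recovers exactly the planted loci - i.e. the background
#' contains no accidental qualifying repeat and no planted run is extended
#' by chance. Rejection is capped at 1000 attempts per contig.
#'
#' @param n number of contigs.
#' @param length_range bp range, inclusive (default 400-800, a typical
#'   assembled EST contig length).
#' @param gc target GC fraction (default 0.40, the composition observed in
#'   conifer transcriptome assemblies).
#' @param ssr_spec NULL, or data.frame(contig, unit, repeats) planting one
#'   run per row into contig index `contig` at a random interior position
#'   (>= 60 bp from either end).
#' @param cds_spec NULL, or TRUE to record a central CDS interval covering
#'   roughly half of each contig (length divisible by 3).
#' @param seed RNG seed.
#' @param cfg the [mining_config()] the round-trip acceptance check uses.
#' @param ensure_design NULL, or a [design_constraints()]: planted-SSR
#'   contigs are additionally rejected until every planted locus admits at
#'   least one primer pair ("clean flanks" in the manifest sense).
#' @return list(seqs, manifest); manifest has elements `contigs`
#'   (data.frame id, length, gc_target, cds_start, cds_end), `ssrs`
#'   (data.frame contig_id, unit, repeats, start, end) and `seed`.
#' @export
generate_contigs <- function(n, length_range = c(400L, 800L), gc = 0.40,
                             ssr_spec = NULL, cds_spec = NULL, seed = 1L,
                             cfg = mining_config(), ensure_design = NULL) {
  stopifnot(n >= 1L, gc > 0, gc < 1)
  with_seed(seed, {
    ids <- sprintf("synth%03d", seq_len(n))
    seqs <- character(n)
    lens <- integer(n)
    cds_start <- rep(NA_integer_, n)
    cds_end <- rep(NA_integer_, n)
    ssr_rows <- list()
    for (i in seq_len(n)) {
      plant <- if (is.null(ssr_spec)) NULL
               else ssr_spec[ssr_spec$contig == i, , drop = FALSE]
      placed <- NULL
      for (attempt in seq_len(1000L)) {
        len <- sample1(length_range[1L]:length_range[2L])
        s <- .random_dna(len, gc)
        ok <- TRUE
        placed <- NULL
        if (!is.null(plant) && nrow(plant)) {
          segs <- strrep(toupper(plant$unit), plant$repeats)
          seg_len <- nchar(segs)
          lo <- 61L
          hi <- len - 60L - seg_len + 1L
          if (any(hi < lo)) { ok <- FALSE }
          else {
            starts <- integer(nrow(plant))
            used <- cbind(integer(0), integer(0))
            for (j in seq_len(nrow(plant))) {
              cand <- sample1(lo:hi[j])
              # non-overlapping placements, 60 bp apart
              tries <- 0L
              while (nrow(used) &&
                     any(cand <= used[, 2L] + 60L &
                         cand + seg_len[j] - 1L >= used[, 1L] - 60L)) {
                cand <- sample1(lo:hi[j])
                tries <- tries + 1L
                if (tries > 50L) { ok <- FALSE; break }
              }
              if (!ok) break
              starts[j] <- cand
              used <- rbind(used, c(cand, cand + seg_len[j] - 1L))
              substr(s, cand, cand + seg_len[j] - 1L) <- segs[j]
            }
            if (ok)
              placed <- data.frame(contig_id = ids[i],
                                   unit = toupper(plant$unit),
                                   repeats = as.integer(plant$repeats),
                                   start = starts,
                                   end = starts + seg_len - 1L,
                                   stringsAsFactors = FALSE)
          }
        }
        if (!ok) next
        found <- detect_ssrs(stats::setNames(s, ids[i]), cfg)
        expected <- if (is.null(placed)) 0L else nrow(placed)
        if (nrow(found) == expected) {
          if (expected > 0L) {
            po <- placed[order(placed$start), ]
            if (!all(found$start == po$start & found$end == po$end &
                     found$unit == po$unit)) next
            placed <- po
            if (!is.null(ensure_design) &&
                !all(vapply(seq_len(nrow(po)), function(j)
                  nrow(design_primers(s, po[j, ], ensure_design)) > 0L,
                  logical(1)))) next
          }
          seqs[i] <- s
          lens[i] <- len
          break
        }
      }
      if (seqs[i] == "")
        stop("infeasible packing for contig ", ids[i],
             " after 1000 attempts", call. = FALSE)
      if (!is.null(placed)) ssr_rows[[length(ssr_rows) + 1L]] <- placed
      if (isTRUE(cds_spec)) {
        cs <- max(1L, as.integer(lens[i] * 0.25))
        clen <- 3L * (as.integer(lens[i] * 0.5) %/% 3L)
        cds_start[i] <- cs
        cds_end[i] <- cs + clen - 1L
      }
    }
    ssrs <- do.call(rbind, ssr_rows)
    if (is.null(ssrs))
      ssrs <- data.frame(contig_id = character(0), unit = character(0),
                         repeats = integer(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
    list(seqs = stats::setNames(seqs, ids),
         manifest = list(
           contigs = data.frame(id = ids, length = lens, gc_target = gc,
                                cds_start = cds_start, cds_end = cds_end,
                                stringsAsFactors = FALSE),
           ssrs = ssrs, seed = seed))
  })
}

#' Default coefficient truths for marker-outcome simulation
#'
#' Binomial (PCR success) truth: intercept 0.5 and an expected-product-size
#' slope of -0.004 per bp (success declines with amplicon length); Poisson
#' (allele count) truth: intercept 0.2 and a repeat-count slope of 0.13
#' (polymorphism grows with repeat number); the remaining covariates are
#' null.
#'
#' @return list(binomial, poisson) of named coefficient vectors.
#' @export
default_glm_truth <- function() {
  list(binomial = c(intercept = 0.5, pipeline_read2Marker = 0,
                    location_others = 0, tm_sum = 0, product_size = -0.004),
       poisson = c(intercept = 0.2, pipeline_read2Marker = 0,
                   location_others = 0, repeat_count = 0.13,
                   unit_length = 0))
}

#' Simulate per-locus marker outcomes
#'
#' Covariates mirror a marker validation panel: design pipeline label,
#' genic location, expected product size (uniform 100-400 bp), primer Tm
#' sum (normal around 120 deg C), maximum repeat count (uniform 4-15) and
#' unit length (2-6). PCR success is drawn binomial-logit and the allele
#' count Poisson-log from the supplied truth.
#'
#' @param n_loci number of loci.
#' @param truth coefficient truths as from [default_glm_truth()].
#' @param seed RNG seed.
#' @return data.frame with covariates plus `success` (0/1) and `na`
#'   (allele count).
#' @export
generate_marker_outcomes <- function(n_loci = 2000L,
                                     truth = default_glm_truth(),
                                     seed = 1L) {
  with_seed(seed, {
    pipeline <- sample(c("CMiB", "read2Marker"), n_loci, replace = TRUE)
    location <- sample(c("coding", "others"), n_loci, replace = TRUE)
    product_size <- round(stats::runif(n_loci, 100, 400))
    tm_sum <- stats::rnorm(n_loci, 120, 3)
    repeat_count <- sample(4:15, n_loci, replace = TRUE)
    unit_length <- sample(2:6, n_loci, replace = TRUE)
    b <- truth$binomial
    eta_b <- b[["intercept"]] +
      b[["pipeline_read2Marker"]] * (pipeline == "read2Marker") +
      b[["location_others"]] * (location == "others") +
      b[["tm_sum"]] * tm_sum + b[["product_size"]] * product_size
    success <- stats::rbinom(n_loci, 1L, stats::plogis(eta_b))
    q <- truth$poisson
    eta_p <- q[["intercept"]] +
      q[["pipeline_read2Marker"]] * (pipeline == "read2Marker") +
      q[["location_others"]] * (location == "others") +
      q[["repeat_count"]] * repeat_count +
      q[["unit_length"]] * unit_length
    na <- stats::rpois(n_loci, exp(eta_p))
    data.frame(pipeline = pipeline, location = location,
               product_size = product_size, tm_sum = tm_sum,
               repeat_count = repeat_count, unit_length = unit_length,
               success = success, na = na, stringsAsFactors = FALSE)
  })
}

#' Packaged motif-by-location count fixture
#'
#' The published motif x estimated-location counts for the 81,284-contig
#' conifer transcriptome survey (grand total 4,059 SSRs: 4,003 pure plus 56
#' compound), as (class, location, count) records ready for
#' [summarize_by_location()]. `class` holds the canonical representative;
#' `label` the traditional printed motif name.
#'
#' @return data.frame (class, label, location, count).
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_ssr_location_counts.tsv",
                      package = "estssr", mustWork = TRUE)
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  out$count <- as.integer(out$count)
  out
}
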