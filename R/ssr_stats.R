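# Summary and inferential statistics for EST-SSR surveys.

.locations <- c("three_prime_utr", "five_prime_utr", "coding", "undetermined")

#' Motif-by-location summary table
#'
#' Cross-tabulates SSR counts by motif class and estimated genic location:
#' di- and trinucleotide loci by canonical class, tetra/penta/hexa and
#' compound loci as unit-length groups. Percentages are available against
#' three explicit denominators via [summary_percent()].
#'
#' @param loci data.frame with columns `location` and either
#'   (`canonical`, `unit_length`, `ssr_type`) as produced by
#'   [detect_ssrs()] + [classify_loci()], or pre-aggregated rows with a
#'   `count` column (class label in `class`).
#' @return object of class `ssr_summary`: a count matrix (rows = classes
#'   and groups, columns = locations plus Total) with row group metadata.
#' @export
summarize_by_location <- function(loci) {
  if ("count" %in% names(loci)) {
    cls <- loci$class
    loc <- loci$location
    cnt <- as.integer(loci$count)
  } else {
    stopifnot(all(c("location", "ssr_type") %in% names(loci)))
    grp <- ifelse(loci$ssr_type == "c", "compound",
                  ifelse(loci$unit_length <= 3L, loci$canonical,
                         c("4" = "tetra", "5" = "penta",
                           "6" = "hexa")[as.character(loci$unit_length)]))
    cls <- grp
    loc <- loci$location
    cnt <- rep(1L, nrow(loci))
  }
  loc[loc == "no_annotation"] <- "undetermined"
  stopifnot(all(loc %in% .locations))
  di <- sort(unique(cls[nchar(cls) == 2L]))
  tri <- sort(unique(cls[nchar(cls) == 3L]))
  groups <- intersect(c("tetra", "penta", "hexa", "compound"), unique(cls))
  rows <- c(di, tri, groups)
  m <- matrix(0L, nrow = length(rows), ncol = length(.locations),
              dimnames = list(rows, .locations))
  agg <- stats::aggregate(cnt, list(cls = cls, loc = loc), sum)
  for (i in seq_len(nrow(agg)))
    m[agg$cls[i], agg$loc[i]] <- m[agg$cls[i], agg$loc[i]] + agg$x[i]
  structure(list(counts = m,
                 unit_group = stats::setNames(
                   c(rep("di", length(di)), rep("tri", length(tri)), groups),
                   rows)),
            class = "ssr_summary")
}

#' @export
print.ssr_summary <- function(x, ...) {
  m <- cbind(x$counts, Total = rowSums(x$counts))
  m <- rbind(m, Total = colSums(m))
  print(m)
  invisible(x)
}

#' Percentages from a summary table
#'
#' @param tab an `ssr_summary`.
#' @param class row name (motif class or group, e.g. `"AT"`, `"tri"`).
#'   A unit-length group name (`"di"`, `"tri"`, ...) selects the subtotal
#'   row of that group.
#' @param location column name, or NULL for the row total.
#' @param denom denominator: `"unit_subtotal"` (all loci of the class's
#'   unit-length group), `"grand"` (all loci), or `"pure"` (all
#'   non-compound loci).
#' @param digits rounding (half away from zero); NULL for unrounded.
#' @return percentage.
#' @export
summary_percent <- function(tab, class, location = NULL,
                            denom = c("unit_subtotal", "grand", "pure"),
                            digits = 1L) {
  stopifnot(inherits(tab, "ssr_summary"))
  denom <- match.arg(denom)
  m <- tab$counts
  grp <- tab$unit_group
  num_rows <- if (class %in% rownames(m)) class else names(grp)[grp == class]
  if (length(num_rows) == 0L) stop("unknown class: ", class, call. = FALSE)
  num <- if (is.null(location)) sum(m[num_rows, , drop = FALSE])
         else sum(m[num_rows, location])
  den <- switch(denom,
    unit_subtotal = sum(m[names(grp)[grp == grp[[num_rows[1L]]]], , drop = FALSE]),
    grand = sum(m),
    pure = sum(m[names(grp)[grp != "compound"], , drop = FALSE]))
  pct <- 100 * num / den
  if (is.null(digits)) pct else round_half_up(pct, digits)
}

#' Subtotals of a summary table
#'
#' @param tab an `ssr_summary`.
#' @return data.frame of counts per unit-length group plus grand and pure
#'   totals.
#' @export
summary_totals <- function(tab) {
  stopifnot(inherits(tab, "ssr_summary"))
  grp <- tab$unit_group
  g <- vapply(split(rownames(tab$counts), grp[rownames(tab$counts)]),
              function(r) sum(tab$counts[r, , drop = FALSE]), numeric(1))
  data.frame(group = c(names(g), "pure", "grand"),
             count = as.integer(c(g, sum(g[names(g) != "compound"]), sum(g))),
             stringsAsFactors = FALSE)
}

#' Fit a generalized linear model with Wald z tests
#'
#' Maximum-likelihood fit (IRLS via `stats::glm`) for binomial-logit or
#' Poisson-log models, reporting per-term estimates, standard errors, Wald
#' z and two-sided normal p-values. Categorical covariates are coded
#' against the supplied reference levels.
#'
#' @param data observation data.frame (>= 10 rows).
#' @param family `"binomial_logit"` or `"poisson_log"`.
#' @param response response column name.
#' @param covariates character vector of covariate column names.
#' @param ref_levels optional named list of reference levels for
#'   categorical covariates.
#' @return list of class `glm_result`: `terms` (data.frame term, estimate,
#'   std_error, z, p), `converged`, `separation`, `deviance`, `fit`.
#' @export
fit_glm <- function(data, family = c("binomial_logit", "poisson_log"),
                    response, covariates, ref_levels = NULL) {
  family <- match.arg(family)
  stopifnot(nrow(data) >= 10L, length(covariates) >= 1L,
            response %in% names(data), all(covariates %in% names(data)))
  for (v in covariates) {
    if (length(unique(data[[v]])) < 2L)
      stop("covariate '", v, "' is constant", call. = FALSE)
    if (is.character(data[[v]]) || is.factor(data[[v]])) {
      lev <- unique(as.character(data[[v]]))
      ref <- ref_levels[[v]] %||% sort(lev)[1L]
      data[[v]] <- stats::relevel(factor(data[[v]]), ref = ref)
    }
  }
  fam <- if (family == "binomial_logit") stats::binomial("logit")
         else stats::poisson("log")
  fml <- stats::reformulate(covariates, response)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = data, family = fam),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|fitted rates numerically 0",
                conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!separation && family == "binomial_logit" &&
      any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8))
    separation <- TRUE
  if (separation)
    warning("possible separation: fitted values at the boundary", call. = FALSE)
  co <- summary(fit)$coefficients
  terms <- data.frame(term = rownames(co), estimate = co[, 1L],
                      std_error = co[, 2L], z = co[, 3L], p = co[, 4L],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(terms = terms, converged = fit$converged,
                 separation = separation, deviance = fit$deviance,
                 fit = fit),
            class = "glm_result")
}

#' Marker diversity statistics (Na, Ho, He, PIC)
#'
#' Allele count, observed heterozygosity, expected heterozygosity
#' `1 - sum(p_i^2)` and polymorphism information content
#' `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2` (Botstein), with allele
#' frequencies taken from the sample. Individuals with any missing call are
#' excluded. Set `unbiased = TRUE` for the small-sample corrected
#' heterozygosity `(2n/(2n-1)) He`.
#'
#' @param allele1,allele2 vectors of allele calls per individual (any
#'   atomic type; NA = missing).
#' @param unbiased apply the sample-size correction to He (default FALSE).
#' @return list(N, Na, Ho, He, PIC).
#' @export
diversity_stats <- function(allele1, allele2, unbiased = FALSE) {
  stopifnot(length(allele1) == length(allele2))
  ok <- !is.na(allele1) & !is.na(allele2)
  if (!any(ok)) stop("all genotype calls missing", call. = FALSE)
  a1 <- as.character(allele1[ok]); a2 <- as.character(allele2[ok])
  n <- length(a1)
  p <- table(c(a1, a2)) / (2 * n)
  he <- 1 - sum(p^2)
  if (unbiased) he <- he * 2 * n / (2 * n - 1)
  pv <- as.numeric(p)
  pic <- 1 - sum(pv^2)
  if (length(pv) > 1L) {
    for (i in seq_len(length(pv) - 1L))
      for (j in (i + 1L):length(pv))
        pic <- pic - 2 * pv[i]^2 * pv[j]^2
  }
  list(N = n, Na = length(pv), Ho = mean(a1 != a2), He = he, PIC = pic)
}

#' GO-term enrichment by Fisher's exact test with BH correction
#'
#' For each term, a 2x2 one-sided (overrepresentation) Fisher exact test of
#' subset membership against term membership among annotated contigs, with
#' Benjamini-Hochberg q-values, sorted by q ascending. The background is
#' the annotated universe outside the subset.
#'
#' @param annotations data.frame with columns contig_id, term (one row per
#'   assignment).
#' @param subset character vector of contig ids (the SSR-containing set);
#'   must be a subset of the annotated universe.
#' @param two_sided use the two-sided test instead (default FALSE).
#' @return data.frame (term, subset_with, subset_without, background_with,
#'   background_without, odds_ratio, p, q).
#' @export
enrich_go <- function(annotations, subset, two_sided = FALSE) {
  stopifnot(all(c("contig_id", "term") %in% names(annotations)))
  universe <- unique(annotations$contig_id)
  subset <- unique(subset)
  if (length(subset) == 0L) stop("empty subset", call. = FALSE)
  if (!all(subset %in% universe))
    stop("subset contains unannotated contigs", call. = FALSE)
  n_sub <- length(subset)
  n_bg <- length(universe) - n_sub
  terms <- unique(annotations$term)
  in_sub <- annotations$contig_id %in% subset
  rows <- lapply(terms, function(tm) {
    with_term <- unique(annotations$contig_id[annotations$term == tm])
    a <- sum(with_term %in% subset)
    cc <- length(with_term) - a
    tab <- matrix(c(a, n_sub - a, cc, n_bg - cc), nrow = 2L)
    ft <- stats::fisher.test(tab, alternative = if (two_sided) "two.sided"
                                                else "greater")
    data.frame(term = tm, subset_with = a, subset_without = n_sub - a,
               background_with = cc, background_without = n_bg - cc,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$q, out$p, out$term), ]
  rownames(out) <- NULL
  out
}

#' Welch two-sample t-test
#'
#' @param a,b numeric samples, each of size >= 2.
#' @return list(t, df, p).
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero variance in both samples", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Spearman and Pearson correlation
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @return list(spearman_r, spearman_p, pearson_r, pearson_p); constant
#'   input yields NA coefficients with a warning.
#' @export
rank_and_linear_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: correlation undefined", call. = FALSE)
    return(list(spearman_r = NA_real_, spearman_p = NA_real_,
                pearson_r = NA_real_, pearson_p = NA_real_))
  }
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  pe <- stats::cor.test(x, y, method = "pearson")
  list(spearman_r = unname(sp$estimate), spearman_p = sp$p.value,
       pearson_r = unname(pe$estimate), pearson_p = pe$p.value)
}

#' Polymorphism forecast from repeat count
#'
#' Calibrated thresholds for di- and trinucleotide loci: di-SSRs with >= 9
#' repeats and tri-SSRs with >= 10 were always polymorphic in the
#' calibration panel, while >= 6 and >= 4 repeats respectively were
#' polymorphic in some cases. Other unit lengths return "possibly" with an
#' `uncalibrated` attribute.
#'
#' @param unit_length repeat unit length (vectorized).
#' @param repeat_count number of repeat units (vectorized).
#' @return character vector over \{"always", "possibly", "unlikely"\} with
#'   attribute `uncalibrated` (logical vector).
#' @export
polymorphism_forecast <- function(unit_length, repeat_count) {
  n <- max(length(unit_length), length(repeat_count))
  unit_length <- rep_len(as.integer(unit_length), n)
  repeat_count <- rep_len(as.integer(repeat_count), n)
  out <- rep("possibly", n)
  di <- unit_length == 2L
  tri <- unit_length == 3L
  out[di] <- ifelse(repeat_count[di] >= 9L, "always",
                    ifelse(repeat_count[di] >= 6L, "possibly", "unlikely"))
  out[tri] <- ifelse(repeat_count[tri] >= 10L, "always",
                     ifelse(repeat_count[tri] >= 4L, "possibly", "unlikely"))
  attr(out, "uncalibrated") <- !(di | tri)
  out
}
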