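# ---------------------------------------------------------------------
# Empirical-null binomial enrichment
#
# Each category (pathway, multicopy, pseudogene-containing) is tested
# with a two-sided exact binomial test: positives are the
# positively-labeled orthogroups in the category, trials are all
# analyzed orthogroups in the category, and the null success
# probability is the genome-wide positive fraction (the empirical
# null), so the question is whether the category departs from the
# table-wide rate, in either direction.
# ---------------------------------------------------------------------

#' Two-sided exact binomial test (minimum-likelihood convention)
#'
#' The two-sided p-value is the sum of P(X = j) over all outcomes j no
#' more probable than the observed k (with the standard 1 + 1e-7
#' relative tolerance on the comparison), X ~ Binomial(n, p0) -- the
#' convention of the classical exact binomial test.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Null success probability in (0, 1).
#' @return The two-sided p-value.
#' @export
binomial_two_sided <- function(k, n, p0) {
  stopifnot(length(k) == 1, length(n) == 1, length(p0) == 1)
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1")
  if (p0 <= 0 || p0 >= 1) stop("need 0 < p0 < 1")
  d <- dbinom(k, n, p0)
  min(1, sum(dbinom(0:n, n, p0)[dbinom(0:n, n, p0) <= d * (1 + 1e-7)]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over the standard step-up FDR adjustment: adjusted
#' values are monotone in rank, capped at 1, and returned in the input
#' order.
#'
#' @param p Vector of p-values in `[0, 1]` (NAs preserved).
#' @return Adjusted p-values.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Category enrichment against the empirical genome-wide rate
#'
#' For every category, counts the analyzed orthogroups and the
#' positives among them, tests the positive fraction against `p0`
#' (default: the positive fraction of the whole supplied results
#' table, recomputed from that table so pre-filtering is respected)
#' with the two-sided exact binomial test, and adjusts across the
#' tested categories with Benjamini-Hochberg.  An orthogroup belonging
#' to several categories is counted once in each.  Categories with no
#' analyzed orthogroup are skipped.
#'
#' @param results data.frame with columns `orthogroup` and `positive`
#'   (logical), one row per analyzed orthogroup (already filtered to
#'   the analysis family, e.g. converged fits only, or
#'   pseudogene-containing orthogroups present in enough genomes).
#' @param categories data.frame with columns `orthogroup` and
#'   `category` (one row per membership).
#' @param p0 Null probability; default the empirical positive fraction
#'   of `results`.
#' @return data.frame category, n, k, p0, p_raw, p_adjusted, direction
#'   (`over`/`under`), sorted by adjusted then raw p.
#' @export
enrich_categories <- function(results, categories, p0 = NULL) {
  stopifnot(all(c("orthogroup", "positive") %in% names(results)),
            all(c("orthogroup", "category") %in% names(categories)))
  if (anyDuplicated(results$orthogroup))
    stop("results must have one row per orthogroup")
  if (is.null(p0)) p0 <- mean(results$positive)
  if (p0 <= 0 || p0 >= 1)
    stop("degenerate empirical null (all or no positives)")
  cats <- categories[categories$orthogroup %in% results$orthogroup, ,
                     drop = FALSE]
  pos_of <- setNames(results$positive, results$orthogroup)
  out <- do.call(rbind, lapply(split(cats$orthogroup, cats$category),
                               function(ogs) {
    ogs <- unique(ogs)
    n <- length(ogs)
    k <- sum(pos_of[ogs])
    data.frame(n = n, k = k,
               p_raw = binomial_two_sided(k, n, p0),
               direction = if (k / n >= p0) "over" else "under")
  }))
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(category = character(0), n = integer(0),
                      k = integer(0), p0 = numeric(0),
                      p_raw = numeric(0), p_adjusted = numeric(0),
                      direction = character(0)))
  out <- data.frame(category = rownames(out), out, row.names = NULL)
  out$p0 <- p0
  out$p_adjusted <- benjamini_hochberg(out$p_raw)
  out <- out[order(out$p_adjusted, out$p_raw, out$category),
             c("category", "n", "k", "p0", "p_raw", "p_adjusted",
               "direction")]
  rownames(out) <- NULL
  out
}

#' Orthogroup filter for pseudogene enrichment
#'
#' The pseudogene-containing enrichment considers only orthogroups
#' with loci present in at least `min_genomes` genomes and carrying at
#' least one pathway annotation, mirroring the thresholds of the
#' selection scan.
#'
#' @param table An `orthogroup_table` (pseudogene assignments already
#'   applied).
#' @param ingroup Genomes whose pseudogenes define a positive.
#' @param min_genomes Minimum number of genomes with loci (default 6).
#' @return data.frame orthogroup, positive -- ready for
#'   [enrich_categories()].
#' @export
pseudogene_enrichment_input <- function(table, ingroup, min_genomes = 6) {
  stopifnot(inherits(table, "orthogroup_table"))
  cc <- table$counts
  present <- tapply(cc$n_intact + cc$n_pseudo > 0, cc$orthogroup, sum)
  has_path <- nzchar(table$annotations$pathways)
  keep <- table$annotations$orthogroup[has_path]
  keep <- intersect(keep, names(present)[present >= min_genomes])
  ing <- cc[cc$genome %in% ingroup & cc$n_pseudo > 0, , drop = FALSE]
  data.frame(orthogroup = sort(keep),
             positive = sort(keep) %in% ing$orthogroup)
}
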