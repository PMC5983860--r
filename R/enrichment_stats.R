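# GSEA-style weighted Kolmogorov-Smirnov enrichment along a score ranking,
# seeded permutation p-values, and the Fisher exact decoupling test.

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Sites are ranked by value descending (ties broken by site index).
#' Walking down the ranking, a hit at rank r moves the running sum up by
#' `|value_r|^exponent / sum_hits |value|^exponent` and a miss moves it
#' down by `1 / (N - N_hits)`; both step families total 1, so the curve
#' starts and ends at 0. The enrichment score is the maximum positive
#' deviation (one-sided: the question is whether hits concentrate at the
#' top). `exponent = 0` recovers the classical unweighted KS statistic;
#' the customary weighted form uses exponent 1. If every hit value is 0
#' the hit steps fall back to equal weights.
#'
#' @param values Numeric ranking values, one per site (e.g. per-site DCA
#'   scores, stability scores, contact counts).
#' @param labels Logical (or 0/1) hit indicator per site; must contain both
#'   hits and misses.
#' @param exponent Weighting exponent >= 0 (default 1).
#' @return Object of class `enrichment_result`: list with `running_sum`
#'   (length N, the curve after each rank), `ES`, `order` (site indices in
#'   ranking order), `n_hits`, `exponent`.
#' @export
ks_enrichment <- function(values, labels, exponent = 1) {
  labels <- as.logical(labels)
  stopifnot(length(values) == length(labels), exponent >= 0,
            !anyNA(values), !anyNA(labels))
  n <- length(values)
  n_hits <- sum(labels)
  if (n_hits == 0L || n_hits == n)
    stop("labels must contain both hits and misses")
  ord <- order(-values, seq_len(n))
  hit <- labels[ord]
  wpow <- abs(values[ord])^exponent
  wsum <- sum(wpow[hit])
  steps <- if (wsum > 0) ifelse(hit, wpow / wsum, -1 / (n - n_hits))
           else ifelse(hit, 1 / n_hits, -1 / (n - n_hits))
  running <- cumsum(steps)
  structure(list(running_sum = running, ES = max(0, running), order = ord,
                 n_hits = n_hits, exponent = exponent, wpow = wpow),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: ES = %.4f (%d hits / %d sites%s)\n",
              x$ES, x$n_hits, length(x$running_sum),
              if (!is.null(x$p_value))
                sprintf(", p = %.4g [%d perms]", x$p_value, x$n_perm)
              else ""))
  invisible(x)
}

#' Permutation p-value for the enrichment score
#'
#' Labels are permuted uniformly `n_perm` times with a seeded generator and
#' the p-value is the +1-corrected upper tail,
#' `p = (1 + #{ES_perm >= ES_obs}) / (1 + n_perm)`, which can never report
#' an exact zero.
#'
#' @inheritParams ks_enrichment
#' @param n_perm Number of label permutations (>= 100; default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return An `enrichment_result` with `p_value`, `n_perm`, `seed` and the
#'   permutation ES vector (`perm_ES`) added.
#' @export
enrichment_pvalue <- function(values, labels, exponent = 1,
                              n_perm = 10000L, seed = NULL) {
  stopifnot(n_perm >= 100L)
  obs <- ks_enrichment(values, labels, exponent)
  if (!is.null(seed)) set.seed(seed)
  perm <- cpp_ks_perm_es(obs$wpow, obs$n_hits, as.integer(n_perm))
  obs$p_value <- (1 + sum(perm >= obs$ES)) / (1 + n_perm)
  obs$n_perm <- as.integer(n_perm)
  obs$seed <- seed
  obs$perm_ES <- perm
  obs
}

#' Fisher exact test for decoupling of co-evolving and polymorphic sites
#'
#' Dichotomises sites by a DCA site-score threshold and by the conservation
#' label (flag = conservation score < `poly_threshold`, the convention of
#' [classify_polymorphic()]) and asks whether the (high-DCA, unflagged)
#' cell -- strongly co-evolving sites that are *not* in the hit set -- is
#' depleted beyond chance: a one-sided exact hypergeometric tail,
#' `p = P(X <= observed)` with the table margins fixed. Computed directly
#' from the hypergeometric mass function, not via a packaged test, so it
#' can be cross-checked against exhaustive enumeration.
#'
#' @param dca_site_scores Numeric per-site DCA scores.
#' @param conservation_scores Numeric per-site conservation scores (same
#'   length).
#' @param dca_threshold High-DCA cut (default 0.1, inclusive `>=`).
#' @param poly_threshold Conservation-label cut (default 0.01, strict `<`).
#' @return Object of class `contingency_result`: list with `table` (2 x 2:
#'   rows high/low DCA, columns flagged/unflagged), `odds_ratio`,
#'   `p_value`, the thresholds, and `depleted_cell`.
#' @export
fisher_decoupling <- function(dca_site_scores, conservation_scores,
                              dca_threshold = 0.1, poly_threshold = 0.01) {
  stopifnot(length(dca_site_scores) == length(conservation_scores))
  ok <- !is.na(dca_site_scores) & !is.na(conservation_scores)
  high <- dca_site_scores[ok] >= dca_threshold
  flagged <- conservation_scores[ok] < poly_threshold
  tab <- matrix(c(sum(high & flagged), sum(high & !flagged),
                  sum(!high & flagged), sum(!high & !flagged)),
                nrow = 2, byrow = TRUE,
                dimnames = list(dca = c("high", "low"),
                                label = c("flagged", "unflagged")))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    stop("degenerate contingency table: empty margin")
  # depletion of the (high DCA, unflagged) cell: X ~ Hypergeom with the
  # unflagged sites as "white balls" and the high-DCA sites as the draw
  x_obs <- tab["high", "unflagged"]
  m <- sum(tab[, "unflagged"]); n_ <- sum(tab[, "flagged"])
  k <- sum(tab["high", ])
  p <- sum(dhyper(0:x_obs, m, n_, k))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  structure(list(table = tab, odds_ratio = or, p_value = p,
                 dca_threshold = dca_threshold,
                 poly_threshold = poly_threshold,
                 depleted_cell = c("high", "unflagged")),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("contingency_result (one-sided exact depletion test)\n")
  print(x$table)
  cat(sprintf("odds ratio = %.4g, p = %.4g (depleted cell: %s/%s)\n",
              x$odds_ratio, x$p_value, x$depleted_cell[1],
              x$depleted_cell[2]))
  invisible(x)
}
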