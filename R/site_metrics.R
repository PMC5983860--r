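# Per-site statistics: collapsing pair scores to sites, entropy-based
# conservation ("polymorphism") scores, and threshold labelling.

#' Collapse ranked pair scores to per-site scores
#'
#' Walks the ranked list top-down; each site receives the score of the
#' first (i.e. highest) pair containing it, and sites that appear in no
#' pair receive 0. Because the list is sorted descending this equals the
#' per-site maximum over all qualifying pairs; sites with score 0 are
#' flagged `in_no_pair`.
#'
#' @param ranked_pairs A [rank_pairs()] result (separation filter already
#'   applied, sorted descending).
#' @param n_sites Total number of sites (defaults to the ranking's own
#'   site count).
#' @return `data.frame` with columns `column`, `dca_site_score`,
#'   `in_no_pair`.
#' @export
pair_to_site_scores <- function(ranked_pairs, n_sites = NULL) {
  if (is.null(n_sites)) n_sites <- attr(ranked_pairs, "n_sites")
  stopifnot(!is.null(n_sites))
  score <- rep(NA_real_, n_sites)
  for (r in seq_len(nrow(ranked_pairs))) {
    s1 <- ranked_pairs$i[r]; s2 <- ranked_pairs$j[r]
    if (is.na(score[s1])) score[s1] <- ranked_pairs$score[r]
    if (is.na(score[s2])) score[s2] <- ranked_pairs$score[r]
  }
  in_no_pair <- is.na(score)
  score[in_no_pair] <- 0
  data.frame(column = seq_len(n_sites), dca_site_score = score,
             in_no_pair = in_no_pair)
}

#' Entropy-based per-site conservation score
#'
#' For each column the non-gap amino-acid frequencies `f_i(A)` are
#' renormalised and scored as `1 + sum_A f_i(A) log f_i(A) / log 20`: one
#' minus the normalised Shannon entropy. A perfectly conserved column
#' scores 1; a column uniform over the 20 amino acids scores 0. Gaps are
#' omitted from the entropy; all-gap columns are returned as `NA`. In the
#' MHC-I literature this quantity is called a "polymorphism score", with
#' the caveat that by the formula *high* values mean *conserved* -- every
#' output column here is therefore named explicitly.
#'
#' @param x An [msa()] (typically a within-species subset, e.g. the human
#'   alleles).
#' @param allele_freqs Optional named numeric vector (sequence id ->
#'   population frequency) weighting each sequence's residues; uniform
#'   weights reproduce the unweighted score. Ids missing from the vector
#'   are dropped.
#' @param n_states Number of amino-acid states normalising the entropy
#'   (default 20; the gap never counts).
#' @return `data.frame` with columns `column`, `conservation_score`
#'   (in [0, 1] or `NA` for all-gap columns).
#' @export
polymorphism_scores <- function(x, allele_freqs = NULL, n_states = 20L) {
  stopifnot(inherits(x, "msa"))
  w <- rep(1, n_seq(x))
  if (!is.null(allele_freqs)) {
    w <- allele_freqs[x$ids]
    keep <- !is.na(w)
    if (!any(keep)) stop("no alignment ids found in allele_freqs")
    x <- msa(x$seqs[keep, , drop = FALSE], ids = x$ids[keep],
             column_map = x$column_map, alphabet = x$alphabet)
    w <- unname(w[keep])
  }
  states <- setdiff(x$alphabet, GAP)
  score <- apply_cols_weighted(x, w, function(col_w) {
    tot <- sum(col_w)
    if (tot <= 0) return(NA_real_)
    f <- col_w / tot
    f <- f[f > 0]
    1 + sum(f * log(f)) / log(n_states)
  }, states)
  data.frame(column = seq_len(n_col(x)), conservation_score = score)
}

# weighted per-state column counts helper (gap excluded via `states`)
apply_cols_weighted <- function(x, w, fn, states) {
  vapply(seq_len(n_col(x)), function(j) {
    col <- x$seqs[, j]
    counts <- vapply(states,
                     function(s) sum(w[col == s]), numeric(1))
    fn(counts)
  }, numeric(1))
}

#' Label sites by a conservation-score threshold
#'
#' Flags sites whose conservation score falls below `threshold`. The
#' convention used throughout the enrichment pipeline follows the source
#' field's wording: flagged sites (score < threshold) are the
#' "non-polymorphic" ones and form the hit set, even though under the
#' entropy formula a *low* score means a *variable* column -- both namings
#' are returned so no downstream consumer has to guess. Customary threshold
#' presets are 0.01 (default), 0.02 and 0.03.
#'
#' @param scores Numeric vector of conservation scores (`NA` = undefined
#'   column, excluded with a warning).
#' @param threshold Threshold in (0, 1).
#' @return `data.frame` with columns `column`, `conservation_score`, `hit`
#'   (score < threshold), `label_quoted` ("non-polymorphic" for hits, the
#'   field's convention) and `label_formula` ("variable" for hits, the
#'   literal entropy reading).
#' @export
classify_polymorphic <- function(scores, threshold = 0.01) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.data.frame(scores)) scores <- scores$conservation_score
  undef <- is.na(scores)
  if (any(undef))
    warning(sum(undef), " undefined (all-gap) column(s) excluded from labelling")
  hit <- scores < threshold
  data.frame(column = seq_along(scores), conservation_score = scores,
             hit = hit,
             label_quoted = ifelse(hit, "non-polymorphic", "polymorphic"),
             label_formula = ifelse(hit, "variable", "conserved"))[!undef, ,
                                                                   drop = FALSE]
}
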