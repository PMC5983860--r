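# Mean-field Direct Coupling Analysis: sequence reweighting, regularised
# frequency estimation, covariance inversion in the reduced gauge, Direct
# Information, and pair ranking.

#' Sequence reweighting and effective sequence number
#'
#' Each sequence a receives a redundancy count
#' `m_a = |{b : identity(a, b) >= identity_threshold}|` (itself included),
#' weight `w_a = 1/m_a`, and the effective number of sequences is
#' `Meff = sum_a 1/m_a`. Identity is the fraction of columns with identical
#' symbols, gaps compared as ordinary symbols. The comparison is inclusive
#' (`>=`) so that duplicated sequences always collapse and `m_a >= 1`.
#'
#' @param x An [msa()].
#' @param identity_threshold Identity threshold in (0, 1); default 0.8.
#' @return Object of class `seq_weights`: list with `m`, `w`, `Meff`.
#' @export
compute_weights <- function(x, identity_threshold = 0.8) {
  stopifnot(inherits(x, "msa"),
            identity_threshold > 0, identity_threshold < 1)
  m <- cpp_redundancy_counts(encode_msa(x), identity_threshold)
  w <- 1 / m
  structure(list(m = m, w = w, Meff = sum(w),
                 identity_threshold = identity_threshold,
                 ids = x$ids),
            class = "seq_weights")
}

#' @export
print.seq_weights <- function(x, ...) {
  cat(sprintf("seq_weights: M = %d, Meff = %.4f (identity >= %.2f)\n",
              length(x$m), x$Meff, x$identity_threshold))
  invisible(x)
}

# Shared frequency builder. X is an M x (L*q) per-sequence state profile:
# one-hot rows for ordinary alignments, or fractional rows when a position
# carries a distribution (expanded ligand rows remain one-hot, so both the
# point and pair formulas reduce to the same weighted cross-product).
.freq_from_profile <- function(X, w, Meff, lambda, q, L, alphabet,
                               col_labels = NULL, partition = NULL) {
  denom <- Meff + lambda
  fi_flat <- (lambda / q + colSums(X * w)) / denom
  fi <- matrix(fi_flat, nrow = q, ncol = L,
               dimnames = list(alphabet, col_labels))
  fij <- (lambda / q^2 + crossprod(X, X * w)) / denom
  # diagonal blocks are the standard closure f_ii(A,B) = delta_AB f_i(A)
  for (i in seq_len(L)) {
    idx <- (i - 1L) * q + seq_len(q)
    fij[idx, idx] <- diag(fi[, i], nrow = q)
  }
  structure(list(fi = fi, fij = fij, q = q, L = L, lambda = lambda,
                 Meff = Meff, alphabet = alphabet,
                 col_labels = col_labels, partition = partition),
            class = "freq_model")
}

.one_hot <- function(enc, q) {
  M <- nrow(enc); L <- ncol(enc)
  X <- matrix(0, M, L * q)
  off <- (rep(seq_len(L), each = M) - 1L) * q
  X[cbind(rep(seq_len(M), L), off + as.vector(enc))] <- 1
  X
}

#' Reweighted, pseudocount-regularised frequencies
#'
#' Single-site and pairwise frequencies with pseudocount mass `lambda`:
#' `f_i(A) = [lambda/q + sum_a w_a d(A, A_i^a)] / (Meff + lambda)` and
#' `f_ij(A,B) = [lambda/q^2 + sum_a w_a d(A, A_i^a) d(B, A_j^a)] /
#' (Meff + lambda)` for `i != j`; diagonal blocks are
#' `f_ii(A,B) = d_AB f_i(A)`. The default pseudocount equals the effective
#' sequence number (`lambda = Meff`).
#'
#' @param x An [msa()].
#' @param weights A [compute_weights()] result, or `NULL` for uniform unit
#'   weights.
#' @param lambda Pseudocount mass >= 0; default `Meff`.
#' @return Object of class `freq_model` with fields `fi` (q x L), `fij`
#'   ((L q) x (L q)), `q`, `L`, `lambda`, `Meff`.
#' @export
compute_frequencies <- function(x, weights = NULL, lambda = NULL) {
  stopifnot(inherits(x, "msa"))
  q <- length(x$alphabet); L <- n_col(x)
  w <- if (is.null(weights)) rep(1, n_seq(x)) else weights$w
  Meff <- sum(w)
  if (is.null(lambda)) lambda <- Meff
  stopifnot(lambda >= 0)
  X <- .one_hot(encode_msa(x), q)
  labels <- if (is.null(x$column_map)) as.character(seq_len(L))
            else as.character(x$column_map)
  .freq_from_profile(X, w, Meff, lambda, q, L, x$alphabet,
                     col_labels = labels)
}

#' Mean-field couplings from the inverted covariance matrix
#'
#' The connected-correlation matrix
#' `C_ij(A,B) = f_ij(A,B) - f_i(A) f_j(B)` is assembled over the reduced
#' alphabet (the last state of each column gauged out, q-1 states each,
#' giving the `(L (q-1))^2` dimension) and inverted; couplings are
#' `e_ij(A,B) = -(C^-1)_ij(A,B)`, zero-padded on the gauged state, with
#' `e_ii = 0` by construction.
#'
#' @param freqs A `freq_model`.
#' @return Object of class `coupling_model` with `e` ((L q) x (L q), padded)
#'   and `reduced_dim`.
#' @export
mean_field_couplings <- function(freqs) {
  stopifnot(inherits(freqs, "freq_model"))
  q <- freqs$q; L <- freqs$L; qr <- q - 1L
  red <- as.vector(outer(seq_len(qr), (seq_len(L) - 1L) * q, "+"))
  C <- freqs$fij[red, red] - tcrossprod(as.vector(freqs$fi[seq_len(qr), ]))
  Cinv <- tryCatch(solve(C), error = function(err) {
    stop(sprintf(paste0("covariance matrix is numerically singular ",
                        "(reciprocal condition number %.3e); a pseudocount ",
                        "lambda > 0 regularises it: %s"),
                 rcond(C), conditionMessage(err)))
  })
  e <- matrix(0, L * q, L * q)
  e[red, red] <- -Cinv
  e <- (e + t(e)) / 2
  for (i in seq_len(L)) {        # intra-column blocks carry no pair coupling
    idx <- (i - 1L) * q + seq_len(q)
    e[idx, idx] <- 0
  }
  structure(list(e = e, q = q, L = L, reduced_dim = L * qr,
                 col_labels = freqs$col_labels,
                 partition = freqs$partition),
            class = "coupling_model")
}

#' Direct Information scores
#'
#' For every column pair a two-site model
#' `P_ij(A,B) ~ exp(e_ij(A,B)) h_i(A) h_j(B)` is built, with the auxiliary
#' fields `h` fixed by multiplicative fixed-point iteration so the model
#' marginals reproduce `f_i` and `f_j`; the Direct Information is the
#' Kullback-Leibler divergence
#' `DI_ij = sum_{A,B} P_ij(A,B) log[P_ij(A,B) / (f_i(A) f_j(B))] >= 0`.
#'
#' @param couplings A `coupling_model`.
#' @param freqs The matching `freq_model`.
#' @param tol Sup-norm tolerance on the marginal mismatch (default 1e-4).
#' @param max_iter Iteration cap per pair (default 100); pairs that fail to
#'   converge are reported via a warning and flagged in the result.
#' @return Object of class `pair_scores`: list with `di` (L x L symmetric,
#'   `NA` diagonal), `converged`, `iterations`, plus column labels and the
#'   intra/inter partition when present.
#' @export
direct_information <- function(couplings, freqs, tol = 1e-4, max_iter = 100L) {
  stopifnot(inherits(couplings, "coupling_model"),
            inherits(freqs, "freq_model"),
            couplings$q == freqs$q, couplings$L == freqs$L)
  res <- cpp_direct_information(couplings$e, freqs$fi, tol, max_iter)
  di <- res$di
  diag(di) <- NA_real_
  dimnames(di) <- list(freqs$col_labels, freqs$col_labels)
  bad <- which(!res$converged & upper.tri(res$converged), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    warning(sprintf("%d pair(s) did not reach tol = %g in %d iterations",
                    nrow(bad), tol, max_iter))
  structure(list(di = di, converged = res$converged,
                 iterations = res$iterations, L = freqs$L,
                 col_labels = freqs$col_labels,
                 partition = freqs$partition),
            class = "pair_scores")
}

#' Run the full mean-field DCA pipeline on an alignment
#'
#' Convenience wrapper: reweighting, frequencies (`lambda = Meff` unless
#' given), covariance inversion, Direct Information.
#'
#' @inheritParams compute_weights
#' @inheritParams compute_frequencies
#' @inheritParams direct_information
#' @return A `pair_scores` object (the `freq_model` and weights are attached
#'   as attributes `freqs` and `weights`).
#' @export
dca <- function(x, identity_threshold = 0.8, lambda = NULL,
                tol = 1e-4, max_iter = 100L) {
  w <- compute_weights(x, identity_threshold)
  f <- compute_frequencies(x, weights = w, lambda = lambda)
  ps <- direct_information(mean_field_couplings(f), f,
                           tol = tol, max_iter = max_iter)
  attr(ps, "freqs") <- f
  attr(ps, "weights") <- w
  ps
}

#' Rank column pairs by score
#'
#' Pairs closer than the minimum sequence separation are excluded
#' (`|i - j| <= min_separation` dropped; the default 4 keeps pairs "over 4
#' amino acids apart"). Ordering is by score descending with deterministic
#' lexicographic `(i, j)` tie-breaking.
#'
#' @param scores A `pair_scores` object or a symmetric numeric matrix.
#' @param min_separation Minimum |i - j| excluded (default 4).
#' @param top_k Optional truncation after ranking.
#' @return `data.frame` of class `ranked_pairs` with columns `i`, `j`,
#'   `score` (and `label_i`, `label_j` when column labels exist).
#' @export
rank_pairs <- function(scores, min_separation = 4L, top_k = NULL) {
  stopifnot(min_separation >= 0)
  m <- if (inherits(scores, "pair_scores")) scores$di else scores
  labels <- if (inherits(scores, "pair_scores")) scores$col_labels
            else colnames(m)
  L <- ncol(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  df <- data.frame(i = ut[, 1L], j = ut[, 2L], score = m[ut])
  df <- df[df$j - df$i > min_separation, , drop = FALSE]
  df <- df[order(-df$score, df$i, df$j), , drop = FALSE]
  if (!is.null(top_k)) df <- head(df, top_k)
  rownames(df) <- NULL
  if (!is.null(labels)) {
    df$label_i <- labels[df$i]
    df$label_j <- labels[df$j]
  }
  structure(df, class = c("ranked_pairs", "data.frame"),
            min_separation = min_separation, n_sites = L)
}

#' Number of top predictions as a fraction of the domain length
#'
#' `floor(frac * L)`: a 178-column domain at the customary 25% gives 44
#' pairs.
#'
#' @param L Domain length (number of columns).
#' @param frac Fraction (default 0.25).
#' @return Integer count.
#' @export
top_fraction_k <- function(L, frac = 0.25) as.integer(floor(frac * L))

#' Write a ranked-pair table as TSV
#'
#' Columns: `i`, `j`, `residue_i`, `residue_j`, `score`, with 1-based
#' structure numbering in the residue columns when a column map exists
#' (column indices repeated otherwise). Header lines start with '#'.
#'
#' @param pairs A `ranked_pairs` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  out <- data.frame(i = pairs$i, j = pairs$j,
                    residue_i = if (!is.null(pairs$label_i)) pairs$label_i
                                else pairs$i,
                    residue_j = if (!is.null(pairs$label_j)) pairs$label_j
                                else pairs$j,
                    score = pairs$score)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# i\tj\tresidue_i\tresidue_j\tscore", con)
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
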