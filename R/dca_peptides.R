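# Joint protein + ligand frequency model: each protein contributes its
# ligand set to K extra alignment columns, every ligand weighted by
# w_a / N_a, so a protein's ligand repertoire enters as a distribution
# rather than a single residue.

#' Build a joint protein-ligand alignment
#'
#' Proteins are matched to their ligand sets; sequences without ligands are
#' excluded (with a message) before construction. Sequence weights are
#' computed on the protein block only, and each ligand of protein a carries
#' weight `w_a / N_a`, so the ligand block of a sequence is a weighted
#' amino-acid distribution whose per-column mass sums to `w_a`. Internally
#' the joint alignment is expanded to one row per (protein, ligand) pair;
#' with those row weights, the standard weighted frequency estimator
#' reproduces the three joint-frequency formulas (ligand point, protein-
#' ligand pair, ligand-ligand pair) exactly.
#'
#' @param x An [msa()] (protein block, L columns).
#' @param ligands A [ligand_set()]; peptide length K fixes the ligand block.
#' @param weights Optional [compute_weights()] result for the *protein*
#'   block; computed at the default 0.8 identity threshold when `NULL`.
#'   Weights are subset and Meff recomputed if ligand matching drops rows.
#' @return Object of class `joint_alignment`: fields `msa` (retained
#'   proteins), `ligands`, `L`, `K`, `enc` (expanded integer matrix, one row
#'   per ligand), `row_weights`, `protein_of_row`, `Meff`, `col_labels`
#'   (protein labels then P1..PK), `partition` (`"protein"`/`"ligand"` per
#'   column).
#' @export
build_joint_alignment <- function(x, ligands, weights = NULL) {
  stopifnot(inherits(x, "msa"), inherits(ligands, "ligand_set"))
  keep <- x$ids %in% names(ligands$peptides)
  if (!any(keep)) stop("no overlap between alignment ids and ligand set")
  if (!all(keep))
    message(sum(!keep), " sequence(s) without ligands excluded from the ",
            "joint alignment")
  prot <- msa(x$seqs[keep, , drop = FALSE], ids = x$ids[keep],
              species = x$species[keep], column_map = x$column_map,
              alphabet = x$alphabet)
  if (is.null(weights)) {
    weights <- compute_weights(prot)
  } else {
    w <- weights$w[match(prot$ids, weights$ids)]
    if (anyNA(w)) stop("weights do not cover the retained sequences")
    weights <- structure(list(m = weights$m[match(prot$ids, weights$ids)],
                              w = w, Meff = sum(w),
                              identity_threshold = weights$identity_threshold,
                              ids = prot$ids),
                         class = "seq_weights")
  }
  K <- ligands$length
  q <- length(prot$alphabet)
  peps <- ligands$peptides[prot$ids]
  n_lig <- vapply(peps, length, 1L)
  pep_chars <- do.call(rbind, strsplit(unlist(peps, use.names = FALSE), ""))
  bad <- !(pep_chars %in% prot$alphabet) | pep_chars == GAP
  if (any(bad)) stop("ligand residues outside the (gap-free) alphabet")
  pep_enc <- matrix(match(pep_chars, prot$alphabet), ncol = K)
  prot_enc <- encode_msa(prot)
  row_of <- rep(seq_len(nrow(prot_enc)), n_lig)
  enc <- cbind(prot_enc[row_of, , drop = FALSE], pep_enc)
  L <- n_col(prot)
  prot_labels <- if (is.null(prot$column_map)) as.character(seq_len(L))
                 else as.character(prot$column_map)
  structure(list(msa = prot, ligands = ligands, L = L, K = K, q = q,
                 alphabet = prot$alphabet, enc = enc,
                 row_weights = unname(weights$w[row_of] / n_lig[row_of]),
                 protein_of_row = row_of, weights = weights,
                 Meff = weights$Meff,
                 col_labels = c(prot_labels, paste0("P", seq_len(K))),
                 partition = rep(c("protein", "ligand"), c(L, K))),
            class = "joint_alignment")
}

#' @export
print.joint_alignment <- function(x, ...) {
  cat(sprintf(
    "joint_alignment: %d proteins (%d ligand rows), %d + %d = %d positions, Meff = %.4f\n",
    n_seq(x$msa), nrow(x$enc), x$L, x$K, x$L + x$K, x$Meff))
  invisible(x)
}

#' Frequencies of the joint protein-ligand model
#'
#' Applies the multi-ligand frequency formulas: ligand point frequencies
#' `f_i(A) = [lambda/q + sum_a (1/m_a) sum_n (1/N_a) d(A, L_in^a)] /
#' (Meff + lambda)`, protein-ligand and ligand-ligand pair frequencies with
#' the analogous `lambda/q^2` pseudocount, and protein-protein entries
#' identical to [compute_frequencies()]. The pseudocount defaults to the
#' protein-block `Meff`, matching the standard model.
#'
#' @param joint A [build_joint_alignment()] result.
#' @param lambda Pseudocount mass >= 0; default `Meff`.
#' @return A `freq_model` over L + K columns whose `partition` field labels
#'   protein vs ligand columns.
#' @export
compute_joint_frequencies <- function(joint, lambda = NULL) {
  stopifnot(inherits(joint, "joint_alignment"))
  if (is.null(lambda)) lambda <- joint$Meff
  stopifnot(lambda >= 0)
  q <- joint$q
  Ltot <- joint$L + joint$K
  X <- .one_hot(joint$enc, q)
  .freq_from_profile(X, joint$row_weights, joint$Meff, lambda, q, Ltot,
                     joint$alphabet, col_labels = joint$col_labels,
                     partition = joint$partition)
}

#' Run DCA on a joint protein-ligand alignment
#'
#' @param joint A [build_joint_alignment()] result.
#' @inheritParams compute_joint_frequencies
#' @inheritParams direct_information
#' @return A `pair_scores` object over L + K columns with the
#'   protein/ligand partition attached.
#' @export
dca_peptides <- function(joint, lambda = NULL, tol = 1e-4, max_iter = 100L) {
  f <- compute_joint_frequencies(joint, lambda = lambda)
  ps <- direct_information(mean_field_couplings(f), f,
                           tol = tol, max_iter = max_iter)
  attr(ps, "freqs") <- f
  ps
}

#' Split pair scores into intra- and inter-molecular rankings
#'
#' Pairs are partitioned by block membership: both columns in the protein
#' block (intra), one in each block (inter), or both in the ligand block
#' (intra-ligand); the three buckets always cover every pair. The sequence-
#' separation filter applies to the intra-protein bucket only -- protein and
#' ligand are distinct chains, so inter-molecular pairs are never
#' separation-filtered. Set `min_separation = 0` to verify the partition is
#' exhaustive.
#'
#' @param scores A `pair_scores` (or symmetric matrix) over L + K columns.
#' @param protein_len Number of protein columns L (taken from the scores'
#'   partition when available).
#' @param min_separation Intra-protein separation filter (default 4).
#' @return List of `ranked_pairs`: `intra`, `inter`, `intra_ligand`. Inter
#'   pairs report ligand columns as P1..PK labels.
#' @export
split_intra_inter <- function(scores, protein_len = NULL,
                              min_separation = 4L) {
  m <- if (inherits(scores, "pair_scores")) scores$di else scores
  if (is.null(protein_len)) {
    part <- if (inherits(scores, "pair_scores")) scores$partition else NULL
    if (is.null(part)) stop("protein_len required when scores carry no partition")
    protein_len <- sum(part == "protein")
  }
  L <- protein_len
  all_pairs <- rank_pairs(m, min_separation = 0L)
  lab <- function(df) {
    if (inherits(scores, "pair_scores")) {
      df$label_i <- scores$col_labels[df$i]
      df$label_j <- scores$col_labels[df$j]
    }
    df
  }
  intra <- all_pairs[all_pairs$j <= L & all_pairs$j - all_pairs$i >
                       min_separation, , drop = FALSE]
  inter <- all_pairs[all_pairs$i <= L & all_pairs$j > L, , drop = FALSE]
  intra_ligand <- all_pairs[all_pairs$i > L, , drop = FALSE]
  out <- lapply(list(intra = intra, inter = inter,
                     intra_ligand = intra_ligand),
                function(df) {
                  rownames(df) <- NULL
                  structure(lab(df), class = c("ranked_pairs", "data.frame"),
                            n_sites = ncol(m))
                })
  out
}
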