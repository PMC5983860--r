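# Seeded generators for every fixture the pipeline needs: Potts alignments
# with planted couplings, protein-ligand datasets with a planted anchor
# rule, toy structures with known geometry, and null/enriched ranking
# fixtures. All generators are pure functions of their spec + seed.

#' Specification of a planted-coupling Potts alignment
#'
#' Sequences are Gibbs-sampled from a pairwise Potts model with zero fields
#' and couplings only on the planted pairs, `J_ij(A, B) = strength *
#' d(A, B)` (a "ferromagnetic" diagonal coupling that favours matching
#' states). Planted pairs respect the sequence-separation rule
#' (|i - j| > 4) and are site-disjoint by default so recovery counts are
#' unambiguous. Columns outside planted pairs are independent and uniform.
#'
#' @param L Number of columns.
#' @param q_sim Simulation alphabet size (default 8; smaller than 21 keeps
#'   brute-force oracles cheap). The alphabet is [aa_alphabet()]`(q_sim)`.
#' @param planted_pairs `data.frame` with columns `i`, `j`, `strength`, or
#'   an integer count: that many disjoint pairs at `strength` are sampled
#'   from the spec's own RNG stream.
#' @param N Number of sequences to emit.
#' @param strength Coupling strength used when `planted_pairs` is a count
#'   (default 1.0, a strong-coupling regime comparable to inferred
#'   couplings in real families).
#' @param burn_in Gibbs burn-in sweeps (default 1000).
#' @param thinning Sweeps between retained samples (default 10).
#' @param min_separation Planted pairs must satisfy |i - j| > this.
#' @param seed Mandatory integer seed.
#' @return Object of class `potts_spec`.
#' @export
potts_spec <- function(L, q_sim = 8L, planted_pairs = 0L, N = 1000L,
                       strength = 1, burn_in = 1000L, thinning = 10L,
                       min_separation = 4L, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.numeric(planted_pairs) && length(planted_pairs) == 1L) {
    n_pairs <- as.integer(planted_pairs)
    planted_pairs <- NULL
  } else {
    n_pairs <- nrow(planted_pairs)
    stopifnot(all(abs(planted_pairs$j - planted_pairs$i) > min_separation),
              all(is.finite(planted_pairs$strength)))
  }
  structure(list(L = as.integer(L), q_sim = as.integer(q_sim),
                 planted_pairs = planted_pairs, n_pairs = n_pairs,
                 N = as.integer(N), strength = strength,
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 min_separation = as.integer(min_separation),
                 seed = as.integer(seed)),
            class = "potts_spec")
}

# sample n site-disjoint pairs with |i-j| > min_sep
.sample_disjoint_pairs <- function(L, n, min_sep) {
  free <- seq_len(L)
  pairs <- matrix(NA_integer_, n, 2L)
  for (p in seq_len(n)) {
    ok <- FALSE
    for (try in 1:1000) {
      ij <- sort(sample(free, 2L))
      if (ij[2L] - ij[1L] > min_sep) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place ", n, " disjoint pairs on L = ", L)
    pairs[p, ] <- ij
    free <- setdiff(free, ij)
  }
  pairs
}

#' Gibbs-sample a Potts alignment with planted couplings
#'
#' @param spec A [potts_spec()].
#' @return An [msa()] over the `q_sim`-letter alphabet, with the realised
#'   planted pairs attached as attribute `planted_pairs`.
#' @export
sample_potts_msa <- function(spec) {
  stopifnot(inherits(spec, "potts_spec"))
  set.seed(spec$seed)
  pp <- spec$planted_pairs
  if (is.null(pp) && spec$n_pairs > 0L) {
    ij <- .sample_disjoint_pairs(spec$L, spec$n_pairs, spec$min_separation)
    pp <- data.frame(i = ij[, 1L], j = ij[, 2L], strength = spec$strength)
  }
  alphabet <- aa_alphabet(spec$q_sim, gap = FALSE)
  if (is.null(pp) || nrow(pp) == 0L) {
    enc <- matrix(sample.int(spec$q_sim, spec$N * spec$L, replace = TRUE),
                  spec$N, spec$L)
  } else {
    J <- lapply(pp$strength,
                function(s) diag(s, spec$q_sim, spec$q_sim))
    enc <- cpp_gibbs_potts(spec$L, spec$q_sim, pp$i, pp$j, J, spec$N,
                           spec$burn_in, spec$thinning)
  }
  chars <- matrix(alphabet[enc], spec$N, spec$L)
  out <- msa(chars, ids = sprintf("sim%05d", seq_len(spec$N)),
             alphabet = alphabet)
  attr(out, "planted_pairs") <- pp
  out
}

#' Specification of a planted protein-ligand coupling
#'
#' Proteins get uniform random residues; each protein carries `n_ligands`
#' peptides whose anchor column is biased by a planted rule: the amino acid
#' at a designated protein column selects (through a fixed random bijection
#' of the alphabet) a preferred anchor amino acid, drawn with probability
#' `preference`; all other ligand columns are uniform. `preference = 1/q`
#' is the no-signal null, `preference = 1` a deterministic anchor.
#'
#' @param M Number of proteins.
#' @param L Protein columns.
#' @param K Ligand columns (peptide length).
#' @param n_ligands Ligands per protein.
#' @param q_sim Alphabet size (default 8).
#' @param rule_column Protein column driving the anchor (default middle).
#' @param anchor_column Ligand anchor position in 1..K (default 2, the
#'   customary P2 anchor).
#' @param preference Probability of the preferred anchor residue, in
#'   (1/q_sim, 1].
#' @param seed Mandatory integer seed.
#' @return Object of class `ligand_coupling_spec`.
#' @export
ligand_coupling_spec <- function(M, L, K, n_ligands = 5L, q_sim = 8L,
                                 rule_column = ceiling(L / 2),
                                 anchor_column = 2L, preference = 1,
                                 seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(preference > 1 / q_sim, preference <= 1,
            anchor_column >= 1L, anchor_column <= K)
  structure(list(M = as.integer(M), L = as.integer(L), K = as.integer(K),
                 n_ligands = as.integer(n_ligands),
                 q_sim = as.integer(q_sim),
                 rule_column = as.integer(rule_column),
                 anchor_column = as.integer(anchor_column),
                 preference = preference, seed = as.integer(seed)),
            class = "ligand_coupling_spec")
}

#' Sample a protein-ligand dataset with a planted anchor rule
#'
#' @param spec A [ligand_coupling_spec()].
#' @return List with `msa` (the proteins), `ligands` (a [ligand_set()]),
#'   and `spec`.
#' @export
sample_ligand_dataset <- function(spec) {
  stopifnot(inherits(spec, "ligand_coupling_spec"))
  set.seed(spec$seed)
  q <- spec$q_sim
  alphabet <- aa_alphabet(q, gap = FALSE)
  prot <- matrix(sample.int(q, spec$M * spec$L, replace = TRUE),
                 spec$M, spec$L)
  mapping <- sample.int(q)  # protein residue -> preferred anchor residue
  peps <- vector("list", spec$M)
  for (a in seq_len(spec$M)) {
    pep <- matrix(sample.int(q, spec$n_ligands * spec$K, replace = TRUE),
                  spec$n_ligands, spec$K)
    pref <- mapping[prot[a, spec$rule_column]]
    use_pref <- runif(spec$n_ligands) < spec$preference
    others <- setdiff(seq_len(q), pref)
    pep[, spec$anchor_column] <- ifelse(
      use_pref, pref, others[sample.int(q - 1L, spec$n_ligands,
                                        replace = TRUE)])
    peps[[a]] <- apply(matrix(alphabet[pep], spec$n_ligands, spec$K), 1L,
                       paste, collapse = "")
  }
  ids <- sprintf("prot%04d", seq_len(spec$M))
  names(peps) <- ids
  list(msa = msa(matrix(alphabet[prot], spec$M, spec$L), ids = ids,
                 alphabet = alphabet),
       ligands = ligand_set(peps, length = spec$K),
       spec = spec)
}

#' Write a minimal toy structure with known geometry
#'
#' Emits a single-chain, single-atom-per-residue PDB file (one CA per
#' residue) so contact maps and precision curves can be tested against
#' hand-computable distances. Geometries: `"line"` (residues spaced
#' `spacing` Angstrom along x), `"helix"` (ideal alpha-helical CA trace:
#' 100 degrees twist, 1.5 Angstrom rise, 2.3 Angstrom radius), `"grid"`
#' (square lattice, `spacing` pitch).
#'
#' @param n_residues Number of residues.
#' @param geometry `"line"`, `"helix"` or `"grid"`.
#' @param spacing Lattice/line spacing in Angstrom (default 4).
#' @param path Output PDB path.
#' @param chain Chain identifier.
#' @return `path`, invisibly.
#' @export
make_toy_structure <- function(n_residues, geometry = c("line", "helix",
                                                        "grid"),
                               spacing = 4, path, chain = "A") {
  geometry <- match.arg(geometry)
  i <- seq_len(n_residues) - 1L
  xyz <- switch(geometry,
    line = cbind(i * spacing, 0, 0),
    helix = cbind(2.3 * cos(i * 100 * pi / 180),
                  2.3 * sin(i * 100 * pi / 180), 1.5 * i),
    grid = {
      side <- ceiling(sqrt(n_residues))
      cbind((i %% side) * spacing, (i %/% side) * spacing, 0)
    })
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n_residues), chain, seq_len(n_residues),
    xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Null or enriched ranking fixture for enrichment calibration
#'
#' Produces `n_sites` ranking values (uniform on (0, 1), sorted descending)
#' and `n_labeled` hit labels. At `enrichment_strength = 0` the labels are
#' placed uniformly at random (the calibration null); at strength 1 the
#' hits occupy the top ranks exactly; intermediate strengths place each hit
#' at the top with that probability and uniformly otherwise.
#'
#' @param n_sites Number of sites.
#' @param n_labeled Number of hit labels.
#' @param enrichment_strength In [0, 1].
#' @param seed Mandatory integer seed.
#' @return List with `values` (descending) and `labels` (logical).
#' @export
sample_ranking_fixture <- function(n_sites, n_labeled,
                                   enrichment_strength = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_labeled >= 1L, n_labeled < n_sites,
            enrichment_strength >= 0, enrichment_strength <= 1)
  set.seed(seed)
  values <- sort(runif(n_sites), decreasing = TRUE)
  labels <- rep(FALSE, n_sites)
  top <- runif(n_labeled) < enrichment_strength
  labels[seq_len(n_labeled)[top]] <- TRUE
  n_rest <- n_labeled - sum(top)
  if (n_rest > 0L)
    labels[sample(which(!labels), n_rest)] <- TRUE
  list(values = values, labels = labels)
}
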