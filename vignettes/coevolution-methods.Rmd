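---
title: "Methods: mean-field DCA with peptide ligands, site metrics, and enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mean-field DCA with peptide ligands, site metrics, and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcapep)
```

# The model and its assumptions

`dcapep` infers directly coupled column pairs of a protein multiple
sequence alignment under a pairwise maximum-entropy (Potts) model, using
the mean-field approximation: couplings are read off the inverse of the
connected-correlation matrix. The method assumes that (i) the alignment
samples a family's sequence space broadly enough that pair correlations are
informative, (ii) phylogenetic relatedness can be corrected crudely by
redundancy reweighting rather than modelled (sequences within 80% identity
share one unit of weight), and (iii) a single pseudocount mass
`λ = Meff` regularises frequencies enough to make the covariance matrix
invertible. None of these assumptions is checked by the package; the
synthetic benchmarks below quantify what they deliver when they hold by
construction.

## Frequencies and reweighting

For sequence `a`, `m_a` is the number of sequences (itself included) with
identity at least the threshold; identity counts gap symbols as ordinary
characters. The threshold comparison is inclusive (`>=`), so duplicate
sequences always collapse and `m_a >= 1` holds; the effective sequence
count is `Meff = Σ 1/m_a`. Frequencies carry a pseudocount `λ` split
uniformly over `q` states (`λ/q` single-site, `λ/q²` pairwise), with
diagonal blocks closed as `f_ii(A,B) = δ_AB f_i(A)` — the standard closure
that makes the covariance well defined.

## Gauge and inversion

The correlation matrix is built on `q − 1` states per column, the **last**
alphabet state (the gap, for protein alignments) gauged out; for a
187-position joint model over 21 states this yields the
`(187·20) × (187·20)` matrix the method is known for. Inversion uses a
dense LAPACK solve; failure raises an error carrying the reciprocal
condition number rather than silently regularising further — with any
positive pseudocount this should not occur.

## Direct Information

Each pair's two-site model `P_ij(A,B) ∝ exp(e_ij(A,B)) h_i(A) h_j(B)` has
its auxiliary fields fixed by multiplicative fixed-point iteration until
the model marginals match `f_i, f_j` to `tol = 1e-4` in sup norm (at most
`max_iter = 100` iterations; non-converged pairs are flagged and reported
via a warning). Neither constant is canonical in the literature; they were
chosen once as the loosest settings under which the package's oracle tests
(independent Nelder–Mead field search) agree to 1e-5 and never revisited.
DI values are clipped at zero only against floating-point round-off.

## Multiple ligands per protein

A protein with ligand set of size `N_a` contributes each ligand with
weight `w_a / N_a`, so its ligand block is a *distribution* over amino
acids. Internally the joint alignment is expanded to one row per
(protein, ligand) pair; the standard weighted frequency estimator on that
expansion reproduces all three published frequency forms (ligand point,
protein–ligand, ligand–ligand) *exactly*, because the ligand–ligand pair
frequency is a sum over single ligands, not a product of two marginal
distributions. Sequence weights are computed on the protein block only, so
at `N_a = 1` for all proteins the joint model is bit-for-bit standard DCA
on the concatenated alignment — the package's strongest internal
correctness check. The pseudocount for joint runs is the protein-block
`Meff` (the printed formula defines `λ = Meff = Σ 1/m_a` with protein-based
`m_a`; whether ligand columns should enter the identity computation is not
stated anywhere, and protein-only weighting is the only reading under
which the reduction property can hold exactly).

Ligand columns share the 21-state alphabet with structurally zero gap
counts (peptides are ungapped); the pseudocount still spreads over all `q`
states, as the printed formulas do. Inter-molecular pairs are never
sequence-separation filtered — protein and peptide are distinct chains —
while intra-protein pairs use the customary `|i − j| > 4` rule.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `identity_threshold` | 0.8 | fraction of columns | the field's customary redundancy cut; inclusive so duplicates collapse |
| `lambda` | `Meff` | pseudo-observations | heavy regularisation typical of mean-field DCA |
| `min_separation` | 4 | residues | "over 4 amino acids apart"; applied intra-chain only |
| `top_fraction` | 0.25 | of domain length | customary top-L/4 prediction budget (178 → 44) |
| contact threshold | 8 (main), 5 (strict) | Å, min heavy-atom distance, inclusive | the two customary contact definitions |
| `poly_threshold` | 0.01 (presets 0.02, 0.03) | conservation-score units | the customary labelling cuts |
| KS `exponent` | 1 | — | standard weighted enrichment; 0 recovers classical KS |
| `n_perm` | 10000 | permutations | p-value resolution ~1e-4 with +1 correction |

# The score-direction disambiguation

The per-site entropy score `1 + Σ f log f / log 20` equals 1 for a
perfectly conserved column and 0 for a uniformly variable one — it is a
*conservation* measure. The literature that motivates this package calls
the same quantity a "polymorphism score" and simultaneously flags sites
with score *below* 0.01 as "non-polymorphic" — readable either as a second,
unstated score direction or as threshold-on-variability phrasing. This
package treats the formula as authoritative, names its output
`conservation_score` everywhere, and `classify_polymorphic()` returns the
flag (`score < threshold`) together with both namings (`label_quoted`,
`label_formula`). The enrichment pipeline uses the flagged set as the hit
set, which matches the quoted convention's "non-polymorphic" yellow-bar
sites. No numerical result in the package depends on which name is used.

# Enrichment statistics

The running sum gains `|v_r|^exponent / Σ_hits |v|^exponent` at hits and
loses `1/(N − N_hits)` at misses; both families total 1, so the curve ends
at 0 and ES — the maximum positive deviation, one-sided by design since the
scientific claim is directional — lies in [0, 1]. Ties in the ranking break
by site index. If every hit has value 0 (possible when ranking by a sparse
site score), hit steps fall back to equal weights rather than 0/0. The
permutation p-value uses a seeded uniform label shuffle and the
`(1 + #{ES* ≥ ES}) / (1 + n_perm)` estimator, which is conservative and
never exactly zero; the source analyses do not state their p-value
machinery, so this standard GSEA-family choice is the package's own.

The Fisher decoupling test dichotomises sites at a DCA site-score cut
(default 0.1, inclusive) and the conservation flag (0.01), and computes the
one-sided hypergeometric tail for *depletion* of the (high-DCA, unflagged)
cell directly from the mass function — deliberately not via
`stats::fisher.test`, so the unit tests can verify it against an
independent enumeration over all tables with the observed margins.

# What the synthetic generators emulate — and what they do not

`sample_potts_msa()` draws Gibbs samples (1000-sweep burn-in, thinning 10,
single chain) from a Potts model with zero fields and couplings only on
planted pairs, `J(A,B) = strength · δ_AB` with `strength = 1` by default —
a strong-coupling regime chosen once to be comparable to the largest
inferred couplings in real families. Planted pairs are site-disjoint and
respect `|i − j| > 4` so recovery counting is unambiguous. The default
simulation alphabet is `q_sim = 8`, keeping brute-force oracles cheap; all
inference code is alphabet-size generic. `sample_ligand_dataset()` plants a
deterministic-to-noisy map from one protein column to a ligand anchor
column (P2 by default, the canonical MHC-I anchor).

These generators reproduce the *statistical* structure the method detects:
planted direct couplings, redundancy, anchor specificity. They do **not**
emulate phylogenetic correlation (the real confounder the reweighting
heuristic only blunts), gap patterns of real alignments, alignment error,
or the long tail of weak couplings real families display. A green recovery
test therefore establishes that the inference machinery is correct, not
that the method would succeed on any particular real family at a given
depth.

# Numerical choices and degenerate inputs

- Column indexing is 1-based throughout (idiomatic R); `column_map` carries
  1-based structure residue numbers. All tie-breaks (pair ranking, ligand
  top-fraction cuts) are lexicographic and documented where they occur.
- Unknown residues (X, B, Z, U, O, J, '*') normalise to the gap so the
  21-state alphabet stays closed; Stockholm '.' gaps unify with '-'.
- Top-fraction ligand retention keeps `max(1, floor(f·n))` peptides — the
  rounding is unstated upstream; the floor-with-minimum-one form guarantees
  a non-empty ligand set.
- All-gap columns yield `NA` conservation scores and are excluded (with a
  warning) from labelling; sites in no separated pair receive site score 0
  and an `in_no_pair` flag rather than being dropped, since their treatment
  upstream is unstated.
- Ranked pairs whose residues are unresolved in the structure are skipped
  in precision curves, not counted false — exclusion avoids penalising
  crystallographic gaps.
- PDB reading is a minimal fixed-width ATOM parser (no R PDB parser is
  available offline here): single model, heavy atoms = non-hydrogen
  including side chains, altloc resolved per atom to highest occupancy. A
  merged peptide chain gets labels P1..PK and a +1000 residue-number offset
  so it is always "sequence-distant" from the protein in long-range contact
  counts, while staying sequence-local to itself.

# Known limitations

- Mean-field inversion is O((L·q)³) memory and time; fine to a few hundred
  columns, not for multi-thousand-column concatenations.
- No average-product correction and no pseudolikelihood inference are
  provided; both are deliberate scope cuts, as is any external predictor
  (ligand prediction, stability calculations — their outputs are imported
  as tables, never computed).
- Permutation p-values are exchangeable-label tests; they do not model
  spatial or phylogenetic correlation between sites.

# What the tests establish

Every quantitative claim above is enforced by the test suite: frequency
formulas by hand-computed fixtures, the covariance inverse by a closed-form
2×2 case, DI by an independent field-search oracle, the ligand reduction to
1e-8, planted recovery at the stated scales (10/10 pairs at L = 30,
N = 5000; 20/20 anchor seeds), type-I error of the permutation test within
[0.03, 0.07] at α = 0.05 over 1000 null replicates, and byte-identical
reruns under a fixed seed. `scripts/acceptance.R` recomputes the same
quantities from scratch at run time; the package reports no number its own
code has not produced.
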