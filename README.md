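# dcapep

Mean-field Direct Coupling Analysis (DCA) for protein families, extended to
joint protein–peptide-ligand alignments, with the downstream statistics
needed to ask whether a family's polymorphic sites avoid its co-evolving and
stability-critical residues. The motivating use case is MHC class I: a
domain family that is highly variable *between* vertebrate species and
highly polymorphic *within* one (human), whose molecules bind short peptides
(typically 9-mers) in a groove with well-known anchor positions (P2, P9).

## Who this is for

Computational structural biologists and immunogeneticists who want, in one
R package and offline:

- contact prediction from a multiple sequence alignment by mean-field DCA;
- a frequency model that admits **multiple peptide ligands per protein**,
  so protein–ligand (inter-molecular) co-evolution can be scored alongside
  intra-protein pairs;
- per-site summaries (pairs-to-sites collapsing, entropy-based
  conservation/"polymorphism" scores) and GSEA-style weighted
  Kolmogorov–Smirnov enrichment with permutation p-values;
- contact-map evaluation (precision curves, per-residue contact counts)
  against PDB structures;
- seeded synthetic generators (planted-coupling Potts alignments, planted
  anchor-rule ligand datasets, toy structures) so every stage is testable
  without downloads.

## The model

Sequences are reweighted by redundancy: `m_a` counts the sequences within
80% identity of sequence `a` (itself included), `w_a = 1/m_a`, and
`Meff = Σ_a 1/m_a` is the effective number of sequences. Frequencies are
regularised with a pseudocount `λ = Meff`:

    f_i(A)    = [λ/q  + Σ_a w_a δ(A, A_i^a)] / (Meff + λ)
    f_ij(A,B) = [λ/q² + Σ_a w_a δ(A, A_i^a) δ(B, A_j^a)] / (Meff + λ)

The connected-correlation matrix `C_ij(A,B) = f_ij − f_i f_j`, built on
`q − 1 = 20` states per column (gap gauged out), is inverted to give
couplings `e_ij = −(C⁻¹)_ij`; each pair's Direct Information is the KL
divergence of its marginal-matched two-site model from the independent
model. With ligands, each of protein `a`'s `N_a` peptides enters the `K`
extra columns with weight `w_a / N_a`, giving a joint `(L+K)`-column model
(178 + 9 = 187 for the MHC-I domain with 9-mers) whose protein–protein
block is exactly standard DCA; inter-molecular pairs are ranked without a
sequence-separation filter because the two molecules are distinct chains.

The per-site conservation score is one minus the normalised Shannon entropy
of a column's non-gap frequencies, `1 + Σ_A f log f / log 20` (1 = perfectly
conserved, 0 = uniform). Note a terminological trap in the MHC literature:
this quantity is often called a "polymorphism score", and the customary
labelling rule flags sites with score **below** a threshold (0.01 by
default) as the "non-polymorphic" hit set used in enrichment; both namings
are exposed explicitly (see `?classify_polymorphic`).

## Worked example

Recover planted couplings from a synthetic Potts alignment:

```r
library(dcapep)
spec <- potts_spec(L = 25, q_sim = 8, planted_pairs = 5L, N = 2000, seed = 7)
aln  <- sample_potts_msa(spec)
top  <- rank_pairs(dca(aln), min_separation = 4, top_k = 5)
as.data.frame(top)[, 1:3]
#>    i  j      score
#> 1 10 19 0.05183916
#> 2 11 18 0.04885316
#> 3  4 12 0.04518832
#> 4 14 23 0.04036837
#> 5  2  7 0.03829349
attr(aln, "planted_pairs")$i  # 10  2 11  4 14 -- all five planted pairs
```

All five top-ranked pairs are the planted ones. The peptide extension finds
a planted protein-column → ligand-anchor rule as the top inter-molecular
pair:

```r
d     <- sample_ligand_dataset(ligand_coupling_spec(
           M = 200, L = 12, K = 9, n_ligands = 5, q_sim = 8,
           preference = 0.9, seed = 11))
joint <- build_joint_alignment(d$msa, d$ligands)
joint
#> joint_alignment: 200 proteins (1000 ligand rows), 12 + 9 = 21 positions, Meff = 200.0000
parts <- split_intra_inter(dca_peptides(joint))
head(as.data.frame(parts$inter)[, c("label_i", "label_j", "score")], 3)
#>   label_i label_j      score
#> 1       6      P2 1.46655054
#> 2      10      P2 0.01564514
#> 3      12      P2 0.01438564
```

The planted rule was protein column 6 → anchor P2; its DI exceeds the
background by two orders of magnitude. Enrichment of a labelled site set at
the top of a ranking, with a seeded permutation p-value:

```r
fx  <- sample_ranking_fixture(60, 12, enrichment_strength = 0.8, seed = 3)
enrichment_pvalue(fx$values, fx$labels, exponent = 1, n_perm = 9999, seed = 5)
#> enrichment_result: ES = 0.9091 (12 hits / 60 sites, p = 0.0001 [9999 perms])
```

ES is the maximum positive running-sum deviation (hits weighted by
|value|^exponent); the p-value is the +1-corrected fraction of label
permutations reaching the observed ES.

## Command line

A single dispatcher exposes the pipeline stages:

```sh
Rscript -e 'dcapep::dca_cli()' dca      --alignment aln.fasta --out pairs.tsv
Rscript -e 'dcapep::dca_cli()' dcapep   --alignment aln.fasta --ligands lig.csv \
    --ligand-length 9 --out-intra intra.tsv --out-inter inter.tsv
Rscript -e 'dcapep::dca_cli()' sites    --pairs pairs.tsv --alignment-subset human.fasta --out sites.tsv
Rscript -e 'dcapep::dca_cli()' contacts --pdb structure.pdb --threshold 5 --out contacts.tsv
Rscript -e 'dcapep::dca_cli()' precision --pairs pairs.tsv --pdb structure.pdb --out curve.tsv
Rscript -e 'dcapep::dca_cli()' enrich   --sites sites.tsv --n-perm 10000 --seed 1 --out enrich.json
Rscript -e 'dcapep::dca_cli()' simulate --kind potts --seed 1 --out sim.fasta
```

(`inst/cli/dcapep` is an equivalent Rscript wrapper.)

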