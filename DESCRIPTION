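Package: dcapep
Title: Mean-Field Direct Coupling Analysis for Proteins and Their Peptide Ligands
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mean-field Direct Coupling Analysis (DCA) of protein multiple
    sequence alignments, with an extension of the frequency model to joint
    protein-ligand alignments in which each protein carries several
    fixed-length peptide ligands. Includes sequence reweighting and effective
    sequence counts, pseudocount-regularised frequency estimation, covariance
    inversion in the reduced gauge, Direct Information scoring, intra- versus
    inter-molecular pair splitting, pairs-to-sites score collapsing,
    entropy-based site conservation scores, residue contact maps and
    precision curves from PDB structures, GSEA-style weighted
    Kolmogorov-Smirnov enrichment with permutation p-values, a Fisher exact
    decoupling test, and seeded synthetic-data generators (Potts alignments
    with planted couplings, ligand datasets with planted anchor rules, toy
    structures, ranking fixtures) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
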