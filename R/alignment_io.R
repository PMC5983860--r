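# Alignment and auxiliary-table input: MSA construction, gap-column
# filtering, species subsetting, ligand tables, per-site annotations and
# allele frequencies.

#' Construct an MSA object
#'
#' An `msa` is a character matrix of aligned single-letter residues (rows =
#' sequences, columns = alignment positions) plus sequence identifiers,
#' optional species labels, an optional `column_map` of 1-based structure
#' residue numbers, and the alphabet the columns live on. Characters outside
#' the alphabet (ambiguity codes X/B/Z/U/O/J, '*', '.') are normalised to the
#' gap symbol so the alphabet stays closed.
#'
#' @param seqs Character matrix (M x L) of single characters, or character
#'   vector of equal-length strings.
#' @param ids Unique sequence identifiers (recycled from names/rownames when
#'   missing).
#' @param species Optional character vector of species labels, one per
#'   sequence.
#' @param column_map Optional integer vector, length L, strictly increasing:
#'   structure residue number of each alignment column.
#' @param alphabet State alphabet; last state is gauged out downstream.
#' @return Object of class `msa`.
#' @export
msa <- function(seqs, ids = NULL, species = NULL, column_map = NULL,
                alphabet = aa_alphabet()) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L)
      stop("ragged alignment: sequences have unequal lengths")
    if (is.null(ids)) ids <- names(seqs)
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  if (is.null(ids)) ids <- rownames(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(seqs)))
  if (anyDuplicated(ids)) stop("sequence identifiers must be unique")
  if (nrow(seqs) < 1L || ncol(seqs) < 1L) stop("empty alignment")
  seqs <- toupper(seqs)
  seqs[!(seqs %in% alphabet)] <- GAP
  if (!(GAP %in% alphabet) && any(seqs == GAP))
    stop("alignment contains symbols outside a gap-free alphabet")
  if (!is.null(species) && length(species) != nrow(seqs))
    stop("species labels must match the number of sequences")
  if (!is.null(column_map)) {
    column_map <- as.integer(column_map)
    if (length(column_map) != ncol(seqs))
      stop("column_map length must equal the number of columns")
    if (any(diff(column_map) <= 0L))
      stop("column_map must be strictly increasing")
  }
  dimnames(seqs) <- list(ids, NULL)
  structure(list(seqs = seqs, ids = ids, species = species,
                 column_map = column_map, alphabet = alphabet),
            class = "msa")
}

#' @export
dim.msa <- function(x) dim(x$seqs)

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns (alphabet q = %d%s)\n",
              nrow(x$seqs), ncol(x$seqs), length(x$alphabet),
              if (!is.null(x$species)) ", species-labelled" else ""))
  invisible(x)
}

#' Number of sequences / columns of an MSA
#' @param x An `msa`.
#' @return Integer.
#' @export
n_seq <- function(x) nrow(x$seqs)

#' @rdname n_seq
#' @export
n_col <- function(x) ncol(x$seqs)

# integer encoding, 1..q, used by all numeric kernels
encode_msa <- function(x) {
  m <- match(x$seqs, x$alphabet)
  dim(m) <- dim(x$seqs)
  storage.mode(m) <- "integer"
  m
}

#' Read a multiple sequence alignment
#'
#' FASTA and Stockholm dialects are parsed with Biostrings; rows are
#' normalised to uppercase, '.' gaps unified to '-', and unknown residues
#' mapped to the gap state.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"stockholm"`.
#' @param species_from Optional: a named character vector (id -> species), or
#'   a regular expression with one capture group applied to identifiers to
#'   extract a species label. Header grammars differ between databases, so
#'   nothing is hard-coded.
#' @param alphabet State alphabet for the resulting [msa()].
#' @return An [msa()].
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm"),
                           species_from = NULL, alphabet = aa_alphabet()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  strs <- if (format == "fasta") {
    as.character(Biostrings::readBStringSet(path, format = "fasta"))
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    setNames(as.character(aln), rownames(aln))
  }
  if (length(strs) == 0L) stop("empty alignment: ", path)
  strs <- chartr(".", "-", toupper(strs))
  species <- NULL
  if (!is.null(species_from)) {
    ids <- names(strs)
    species <- if (length(species_from) > 1L || !is.null(names(species_from))) {
      unname(species_from[ids])
    } else {
      m <- regmatches(ids, regexec(species_from, ids))
      vapply(m, function(g) if (length(g) >= 2L) g[2L] else NA_character_, "")
    }
  }
  msa(strs, ids = names(strs), species = species, alphabet = alphabet)
}

#' Write an MSA to FASTA
#' @param x An `msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  lines <- character(2L * n_seq(x))
  lines[c(TRUE, FALSE)] <- paste0(">", x$ids)
  lines[c(FALSE, TRUE)] <- apply(x$seqs, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Remove highly gapped alignment columns
#'
#' Columns whose gap fraction is strictly greater than `max_gap_fraction`
#' are dropped. The `column_map` records the surviving columns: an existing
#' map is subset, otherwise the surviving original (1-based) column indices
#' are stored, so positions remain traceable to the input numbering.
#'
#' @param x An `msa`.
#' @param max_gap_fraction Columns with gap fraction > this are removed
#'   (default 0.7, i.e. the ">70%" rule).
#' @return Filtered `msa`.
#' @export
filter_gap_columns <- function(x, max_gap_fraction = 0.7) {
  stopifnot(max_gap_fraction > 0, max_gap_fraction <= 1)
  gap_frac <- colMeans(x$seqs == GAP)
  keep <- which(gap_frac <= max_gap_fraction)
  if (length(keep) == 0L) stop("all columns exceed the gap-fraction threshold")
  map <- if (is.null(x$column_map)) keep else x$column_map[keep]
  msa(x$seqs[, keep, drop = FALSE], ids = x$ids, species = x$species,
      column_map = map, alphabet = x$alphabet)
}

#' Subset an alignment by species
#'
#' Rows are filtered by inclusion/exclusion lists. When `max_per_species` is
#' given, every species represented by more than that many sequences is
#' dropped entirely (the "remove species with > 500 sequences" experiment),
#' not down-sampled.
#'
#' @param x An `msa` with species labels.
#' @param include,exclude Character vectors of species to keep / drop
#'   (`NULL` = no constraint). They must not overlap.
#' @param max_per_species Drop whole species with more sequences than this.
#' @return Subset `msa` (column count unchanged).
#' @export
subset_by_species <- function(x, include = NULL, exclude = NULL,
                              max_per_species = NULL) {
  if (is.null(x$species)) stop("msa carries no species labels")
  if (!is.null(include) && !is.null(exclude) &&
      length(intersect(include, exclude)) > 0L)
    stop("include and exclude lists overlap")
  keep <- rep(TRUE, n_seq(x))
  if (!is.null(include)) keep <- keep & x$species %in% include
  if (!is.null(exclude)) keep <- keep & !(x$species %in% exclude)
  if (!is.null(max_per_species)) {
    tab <- table(x$species)
    big <- names(tab)[tab > max_per_species]
    keep <- keep & !(x$species %in% big)
  }
  if (!any(keep)) stop("species subsetting removed every sequence")
  msa(x$seqs[keep, , drop = FALSE], ids = x$ids[keep],
      species = x$species[keep], column_map = x$column_map,
      alphabet = x$alphabet)
}

#' Construct a ligand set
#'
#' A `ligand_set` maps sequence identifiers to their fixed-length peptide
#' ligands (e.g. the 9-mers presented by an MHC-I allele).
#'
#' @param peptides Named list: sequence id -> character vector of peptides,
#'   all of length `length`.
#' @param length Required peptide length K.
#' @return Object of class `ligand_set` with fields `peptides`, `n_ligands`,
#'   `length`.
#' @export
ligand_set <- function(peptides, length = 9L) {
  if (is.null(names(peptides)) || any(names(peptides) == ""))
    stop("peptides must be a named list keyed by sequence id")
  peptides <- lapply(peptides, toupper)
  ok <- vapply(peptides, function(p) all(nchar(p) == length), TRUE)
  if (!all(ok)) stop("all peptides must have length ", length)
  n <- vapply(peptides, base::length, 1L)
  if (any(n < 1L)) stop("every retained entry needs at least one ligand")
  structure(list(peptides = peptides, n_ligands = n,
                 length = as.integer(length)),
            class = "ligand_set")
}

#' @export
print.ligand_set <- function(x, ...) {
  cat(sprintf("ligand_set: %d sequences, %d ligands of length %d\n",
              length(x$peptides), sum(x$n_ligands), x$length))
  invisible(x)
}

#' Read a per-sequence peptide ligand table
#'
#' Supported dialects: `"csv"` -- columns `sequence_id,peptide[,score]`;
#' `"prediction"` -- same columns with `score` required (binding-prediction
#' output), where `top_fraction` keeps, per sequence, the best-scoring
#' fraction of peptides. Peptides whose length differs from `length` are
#' dropped first. The per-sequence retention count is
#' `max(1, floor(top_fraction * n))`; ties at the cutoff are broken by
#' peptide lexicographic order so selection is deterministic.
#'
#' @param path CSV/TSV file (separator sniffed from the header line).
#' @param format `"csv"` or `"prediction"`.
#' @param length Required peptide length K (default 9).
#' @param top_fraction Optional fraction in (0, 1] of best-scoring peptides
#'   retained per sequence.
#' @param best `"high"` if larger scores are better (default), `"low"` for
#'   rank-like scores.
#' @return A [ligand_set()].
#' @export
read_ligands <- function(path, format = c("csv", "prediction"), length = 9L,
                         top_fraction = NULL, best = c("high", "low")) {
  format <- match.arg(format)
  best <- match.arg(best)
  if (!file.exists(path)) stop("ligand table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (!all(c("sequence_id", "peptide") %in% names(tab)))
    stop("ligand table needs columns sequence_id and peptide")
  if (format == "prediction" && !("score" %in% names(tab)))
    stop("prediction dialect requires a score column")
  tab$peptide <- toupper(tab$peptide)
  tab <- tab[nchar(tab$peptide) == length, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no ligands of length ", length, " in ", path)
  split_tab <- split(tab, tab$sequence_id)
  peps <- lapply(split_tab, function(d) {
    if (!is.null(top_fraction)) {
      stopifnot(top_fraction > 0, top_fraction <= 1)
      sc <- if (best == "high") -d$score else d$score
      d <- d[order(sc, d$peptide), , drop = FALSE]
      d <- head(d, max(1L, floor(top_fraction * nrow(d))))
    }
    d$peptide
  })
  ligand_set(peps, length = length)
}

#' Read a per-site annotation table
#'
#' Imports external per-site tables (e.g. alanine-scan stability output) as
#' a site table keyed by alignment column. Input records are
#' `(position, value)` pairs; `kind` says whether positions are structure
#' residue numbers (mapped back through the alignment's `column_map`) or
#' alignment column indices.
#'
#' @param path TSV/CSV with columns `position` and `value` (lines starting
#'   with '#' ignored).
#' @param kind `"residue"` (needs `column_map`) or `"column"`.
#' @param column_map Structure residue number per alignment column, required
#'   for `kind = "residue"`.
#' @param n_col Number of alignment columns (bound check for
#'   `kind = "column"`).
#' @return `data.frame` with columns `column` and `value`, class
#'   `site_table`.
#' @export
read_site_annotations <- function(path, kind = c("residue", "column"),
                                  column_map = NULL, n_col = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", sub("^#\\s*", "", header))) "\t" else ","
  tab <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expected (position, value) records")
  names(tab)[1:2] <- c("position", "value")
  col <- if (kind == "residue") {
    if (is.null(column_map)) stop("kind = 'residue' requires a column_map")
    hit <- match(tab$position, column_map)
    if (anyNA(hit))
      stop("residue numbers outside the column_map: ",
           paste(tab$position[is.na(hit)], collapse = ", "))
    hit
  } else {
    if (!is.null(n_col) && any(tab$position < 1L | tab$position > n_col))
      stop("column indices out of range")
    as.integer(tab$position)
  }
  if (anyDuplicated(col)) stop("duplicate column entries in site table")
  out <- data.frame(column = col, value = tab$value)
  if (ncol(tab) > 2L) out <- cbind(out, tab[, -(1:2), drop = FALSE])
  class(out) <- c("site_table", "data.frame")
  out[order(out$column), , drop = FALSE]
}

#' Read an allele-frequency table
#'
#' @param path CSV/TSV with columns `allele` and `frequency`.
#' @param floor Minimum frequency retained (default 1e-5, the "frequency
#'   exceeding 0.00001" rule).
#' @return Named numeric vector of frequencies, alleles below the floor
#'   dropped.
#' @export
read_allele_freqs <- function(path, floor = 1e-5) {
  if (!file.exists(path)) stop("allele table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expected (allele, frequency) records")
  freq <- as.numeric(tab[[2L]])
  if (any(freq < 0)) stop("negative allele frequency")
  keep <- freq > floor
  setNames(freq[keep], tab[[1L]][keep])
}
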