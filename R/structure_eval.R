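# Contact maps and precision curves from protein structures. A minimal
# fixed-width PDB ATOM-record reader is used (single model, heavy atoms,
# altloc resolved by highest occupancy); no PDB parser ships with the
# pre-installed stack.

#' Read residue heavy-atom coordinates from a PDB file
#'
#' Parses ATOM records of a single-model PDB file. Hydrogens are excluded
#' ("heavy atoms" = everything else, side chains included); alternate
#' locations are resolved per atom to the highest-occupancy record. A
#' peptide chain can be merged onto the protein chain, its residues
#' relabelled `P1..PK` in residue-number order -- the merged-chain
#' convention used when a receptor and its bound ligand are analysed as one
#' entity.
#'
#' @param pdb_path Path to a PDB file.
#' @param chains Chain identifiers to read (default: first chain found).
#' @param peptide_chain Optional chain merged onto the result with `P`
#'   labels.
#' @return Object of class `residue_coords`: list of residues (named by
#'   label: the residue number as character, or `P1..PK`), each a numeric
#'   matrix of heavy-atom xyz; attributes `resno` (numeric residue order
#'   used for sequence separation; peptide residues continue after the
#'   protein) and `chain`.
#' @export
read_structure <- function(pdb_path, chains = NULL, peptide_chain = NULL) {
  if (!file.exists(pdb_path)) stop("structure file not found: ", pdb_path)
  lines <- readLines(pdb_path)
  lines <- lines[startsWith(lines, "ATOM")]
  end <- grep("^ENDMDL", lines)  # single-model contract
  if (length(end) > 0L) lines <- lines[seq_len(end[1L] - 1L)]
  if (length(lines) == 0L) stop("no ATOM records in ", pdb_path)
  fw <- function(a, b) trimws(substr(lines, a, b))
  atoms <- data.frame(
    name = fw(13, 16), altloc = fw(17, 17), chain = fw(22, 22),
    resno = as.integer(fw(23, 26)),
    x = as.numeric(fw(31, 38)), y = as.numeric(fw(39, 46)),
    z = as.numeric(fw(47, 54)),
    occ = suppressWarnings(as.numeric(fw(55, 60))),
    elem = fw(77, 78), stringsAsFactors = FALSE)
  atoms$occ[is.na(atoms$occ)] <- 1
  # heavy atoms only: trust the element column when present, else atom name
  is_h <- ifelse(atoms$elem != "", atoms$elem %in% c("H", "D"),
                 grepl("^[0-9]*H", atoms$name))
  atoms <- atoms[!is_h, , drop = FALSE]
  if (is.null(chains)) chains <- atoms$chain[1L]
  missing <- setdiff(c(chains, peptide_chain), unique(atoms$chain))
  if (length(missing) > 0L)
    stop("chain(s) not present in structure: ", paste(missing, collapse = ", "))
  pick_alt <- function(d) {
    if (all(d$altloc %in% c("", "A"))) return(d[d$altloc %in% c("", "A"), ])
    keep <- unlist(lapply(split(seq_len(nrow(d)), d$name), function(ix) {
      ix[which.max(d$occ[ix])]
    }))
    d[sort(keep), , drop = FALSE]
  }
  collect <- function(ch, label_fn) {
    d <- atoms[atoms$chain %in% ch, , drop = FALSE]
    res <- split(d, d$resno)
    res <- res[order(as.integer(names(res)))]
    coords <- lapply(res, function(r) {
      r <- pick_alt(r)
      unname(as.matrix(r[, c("x", "y", "z")]))
    })
    names(coords) <- label_fn(as.integer(names(res)))
    list(coords = coords, resno = as.integer(names(res)))
  }
  prot <- collect(chains, function(n) as.character(n))
  coords <- prot$coords
  resno <- prot$resno
  if (!is.null(peptide_chain)) {
    pep <- collect(peptide_chain, function(n) paste0("P", seq_along(n)))
    coords <- c(coords, pep$coords)
    # peptide continues after the protein in separation space: a different
    # chain never counts as sequence-local
    resno <- c(resno, max(resno) + 1000L + seq_along(pep$coords))
  }
  structure(coords, class = "residue_coords", resno = resno,
            chain = chains)
}

#' @export
print.residue_coords <- function(x, ...) {
  cat(sprintf("residue_coords: %d residues, %d heavy atoms\n",
              length(x), sum(vapply(x, nrow, 1L))))
  invisible(x)
}

# minimum heavy-atom distance between two residues' atom sets
.min_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Residue-residue contact map
#'
#' The distance between two residues is the minimum over all heavy-atom
#' pairs; two residues are in contact when that distance is less than or
#' equal to `threshold` (inclusive). 8 Angstrom is the customary contact
#' definition, 5 Angstrom the stricter sensitivity variant.
#'
#' @param coords A [read_structure()] result.
#' @param threshold Contact threshold in Angstrom (> 0), default 8.
#' @return Object of class `contact_map`: list with `dist` (symmetric
#'   matrix of minimum distances, 0 diagonal), `contact` (logical matrix),
#'   `threshold`, `resno`.
#' @export
contact_map <- function(coords, threshold = 8) {
  stopifnot(inherits(coords, "residue_coords"), threshold > 0)
  n <- length(coords)
  d <- matrix(0, n, n, dimnames = list(names(coords), names(coords)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        d[i, j] <- d[j, i] <- .min_dist(coords[[i]], coords[[j]])
      }
    }
  }
  contact <- d <= threshold
  diag(contact) <- FALSE
  structure(list(dist = d, contact = contact, threshold = threshold,
                 resno = attr(coords, "resno")),
            class = "contact_map")
}

#' Precision of ranked pair predictions against a contact map
#'
#' For k = 1..k_max, `precision(k) = TP(k) / k` over the top-k ranked
#' pairs. Pair columns are translated to structure residue labels through
#' `column_map`; pairs whose residues are unresolved in the structure are
#' skipped entirely rather than counted false, so crystallographic gaps do
#' not masquerade as wrong predictions.
#'
#' @param ranked_pairs A [rank_pairs()] result.
#' @param cmap A [contact_map()].
#' @param column_map Structure residue number per alignment column; when
#'   `NULL`, ranked-pair labels (or column indices) are matched to contact
#'   map residue names directly.
#' @param k_max Curve length (default 900, capped at the number of mappable
#'   pairs).
#' @return `data.frame` of class `precision_curve` with columns `k`,
#'   `true_positives`, `precision`.
#' @export
precision_curve <- function(ranked_pairs, cmap, column_map = NULL,
                            k_max = 900L) {
  stopifnot(inherits(cmap, "contact_map"))
  res_names <- rownames(cmap$dist)
  lab_i <- if (!is.null(column_map)) as.character(column_map[ranked_pairs$i])
           else if (!is.null(ranked_pairs$label_i)) ranked_pairs$label_i
           else as.character(ranked_pairs$i)
  lab_j <- if (!is.null(column_map)) as.character(column_map[ranked_pairs$j])
           else if (!is.null(ranked_pairs$label_j)) ranked_pairs$label_j
           else as.character(ranked_pairs$j)
  mi <- match(lab_i, res_names)
  mj <- match(lab_j, res_names)
  ok <- !is.na(mi) & !is.na(mj)
  if (!any(ok)) stop("no ranked pair maps onto the structure")
  hits <- cmap$contact[cbind(mi[ok], mj[ok])]
  k_max <- min(k_max, length(hits))
  tp <- cumsum(hits)[seq_len(k_max)]
  structure(data.frame(k = seq_len(k_max), true_positives = tp,
                       precision = tp / seq_len(k_max)),
            class = c("precision_curve", "data.frame"),
            n_skipped = sum(!ok))
}

#' Number of structural contacts per residue
#'
#' Counts, for each residue, the other residues whose minimum heavy-atom
#' distance is at most `threshold` (default 5 Angstrom; self excluded).
#' Merged peptide residues both receive and contribute counts.
#'
#' @param coords A [read_structure()] result (or a [contact_map()], reused
#'   directly).
#' @param threshold Distance threshold in Angstrom.
#' @return `data.frame` with columns `residue` (label) and `n_contacts`.
#' @export
contacts_per_site <- function(coords, threshold = 5) {
  cm <- if (inherits(coords, "contact_map")) {
    stopifnot(isTRUE(all.equal(coords$threshold, threshold)))
    coords
  } else contact_map(coords, threshold)
  data.frame(residue = rownames(cm$dist), n_contacts = rowSums(cm$contact),
             row.names = NULL)
}

#' Long-range contacts per residue
#'
#' As [contacts_per_site()] but counting only partners more than
#' `min_separation` apart in residue numbering (merged peptide residues are
#' offset so they always count as sequence-distant from the protein).
#'
#' @inheritParams contacts_per_site
#' @param min_separation Partners with |delta residue number| <= this are
#'   ignored (default 4).
#' @return `data.frame` with columns `residue` and `n_contacts`.
#' @export
long_range_contacts_per_site <- function(coords, threshold = 5,
                                         min_separation = 4L) {
  cm <- if (inherits(coords, "contact_map")) coords
        else contact_map(coords, threshold)
  sep <- abs(outer(cm$resno, cm$resno, "-")) > min_separation
  data.frame(residue = rownames(cm$dist),
             n_contacts = rowSums(cm$contact & sep), row.names = NULL)
}
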