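# Domain definitions, atom selection and the residue classification table
# behind the contact metrics.

#' Define a domain by a residue range
#'
#' Domains are closed residue-number intervals on one chain, 1-based as in
#' the PDB (e.g. a pseudokinase domain spanning residues 523-816 of chain A).
#'
#' @param label domain label used in reports.
#' @param chain one-character chain identifier.
#' @param first,last first and last residue numbers (inclusive).
#' @return a one-row tibble with columns label, chain, first, last.
#' @export
domain_def <- function(label, chain, first, last) {
  stopifnot(is.character(label), nchar(chain) == 1)
  first <- as.integer(first)
  last <- as.integer(last)
  if (first > last) stop("`first` must be <= `last`")
  tibble::tibble(label = label, chain = chain, first = first, last = last)
}

#' Select atoms from a structure or ensemble
#'
#' Filters by domain (chain + closed residue interval), explicit residue
#' numbers and/or atom names, preserving atom order. Selecting on an
#' ensemble subsets every frame identically, so frame extraction and
#' selection commute.
#'
#' @param x an atom tibble or a `td_ensemble`.
#' @param domain a [domain_def()] row (or a tibble of several; their union
#'   is taken), or `NULL`.
#' @param atoms character vector of atom names to keep (e.g. `"CA"`), or
#'   `NULL` for all.
#' @param resno integer vector of residue numbers to keep, or `NULL`.
#' @param chain chain to keep when `domain` is `NULL`.
#' @return an object of the same type as `x` restricted to the selection.
#' @export
select_atoms <- function(x, domain = NULL, atoms = NULL, resno = NULL,
                         chain = NULL) {
  UseMethod("select_atoms")
}

selection_mask <- function(tbl, domain, atoms, resno, chain) {
  keep <- rep(TRUE, nrow(tbl))
  if (!is.null(domain)) {
    dkeep <- rep(FALSE, nrow(tbl))
    for (i in seq_len(nrow(domain))) {
      dkeep <- dkeep | (tbl$chain == domain$chain[i] &
                          tbl$resno >= domain$first[i] &
                          tbl$resno <= domain$last[i])
    }
    keep <- keep & dkeep
  }
  if (!is.null(chain)) keep <- keep & tbl$chain %in% chain
  if (!is.null(resno)) keep <- keep & tbl$resno %in% resno
  if (!is.null(atoms)) keep <- keep & tbl$name %in% atoms
  keep
}

#' @export
select_atoms.data.frame <- function(x, domain = NULL, atoms = NULL,
                                    resno = NULL, chain = NULL) {
  assert_structure(x)
  keep <- selection_mask(x, domain, atoms, resno, chain)
  if (!any(keep))
    stop("empty selection: no atoms match the requested domain/atom filter",
         call. = FALSE)
  x[keep, , drop = FALSE]
}

#' @export
select_atoms.td_ensemble <- function(x, domain = NULL, atoms = NULL,
                                     resno = NULL, chain = NULL) {
  keep <- selection_mask(x$atoms, domain, atoms, resno, chain)
  if (!any(keep))
    stop("empty selection: no atoms match the requested domain/atom filter",
         call. = FALSE)
  cols <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1,
                          3 * which(keep)))
  new_ensemble(x$atoms[keep, , drop = FALSE], x$xyz[, cols, drop = FALSE])
}

#' Residue classification table for interface metrics
#'
#' Per 3-letter residue code: hydrophobic / positive / negative / aromatic
#' flags and the named atom groups the contact detectors use (charged-group
#' atoms for ionic contacts and salt bridges; ring atoms for aromatic
#' stacking centroids). The defaults mirror common protein-interaction
#' contact-server conventions and can be overridden by passing an edited
#' copy to the contact functions.
#'
#' @return a tibble with columns resname, hydrophobic, positive, negative,
#'   aromatic, charged_atoms (list), ring_atoms (list).
#' @export
residue_classes <- function() {
  hydrophobic <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO",
                   "TYR")
  positive <- c("LYS", "ARG", "HIS")
  negative <- c("ASP", "GLU")
  aromatic <- c("PHE", "TYR", "TRP", "HIS")
  charged <- list(
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), LYS = "NZ",
    ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2")
  )
  rings <- list(
    PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
  )
  codes <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")
  tibble::tibble(
    resname = codes,
    hydrophobic = codes %in% hydrophobic,
    positive = codes %in% positive,
    negative = codes %in% negative,
    aromatic = codes %in% aromatic,
    charged_atoms = lapply(codes, function(r) charged[[r]] %||% character(0)),
    ring_atoms = lapply(codes, function(r) rings[[r]] %||% character(0))
  )
}

# Side-chain heavy atoms = all heavy atoms minus the backbone.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

sidechain_atoms <- function(structure) {
  structure[!(structure$name %in% BACKBONE_ATOMS), , drop = FALSE]
}
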