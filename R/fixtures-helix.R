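# Ideal-geometry peptide builder. Backbones are grown residue by residue
# from standard bond lengths/angles at user-supplied (phi, psi) dihedrals
# (NeRF internal-coordinate placement); side chains are added from idealised
# templates so the class-based interface metrics (hydrophobic, charged,
# aromatic-ring atoms) have real geometry to work with. These generators are
# deterministic test beds that emulate the statistical structure of real
# ensembles, not their physics.

AA_3LETTER <- c(
  A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
  H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
  Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL", Y = "TYR"
)

# Bond lengths (A) and angles (deg) for the peptide backbone.
BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
           ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
           ang_ca_c_o = 120.8)

# Side-chain templates: each atom is placed by place_atom(a, b, c, ...) so
# that dihedral(a, b, c, atom) equals `tors`. Torsions named chi1..chi4 are
# substituted from the residue's rotamer; numeric strings are fixed.
sc_row <- function(name, a, b, c, length, angle, tors) {
  data.frame(name = name, a = a, b = b, c = c, length = length,
             angle = angle, tors = as.character(tors),
             stringsAsFactors = FALSE)
}

sidechain_template <- function(resname) {
  cb <- sc_row("CB", "N", "C", "CA", 1.530, 110.1, "122.6")
  ring6 <- function(stem) rbind(
    sc_row("CD1", "CA", "CB", stem, 1.390, 120.0, "chi2"),
    sc_row("CD2", "CD1", "CB", stem, 1.390, 120.0, "180"),
    sc_row("CE1", "CB", stem, "CD1", 1.390, 120.0, "180"),
    sc_row("CE2", "CB", stem, "CD2", 1.390, 120.0, "180"),
    sc_row("CZ", stem, "CD1", "CE1", 1.390, 120.0, "0")
  )
  switch(resname,
    GLY = NULL,
    ALA = cb,
    SER = rbind(cb, sc_row("OG", "N", "CA", "CB", 1.417, 110.8, "chi1")),
    CYS = rbind(cb, sc_row("SG", "N", "CA", "CB", 1.808, 113.8, "chi1")),
    THR = rbind(cb,
      sc_row("OG1", "N", "CA", "CB", 1.433, 109.6, "chi1"),
      sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1 + 120")),
    VAL = rbind(cb,
      sc_row("CG1", "N", "CA", "CB", 1.527, 110.5, "chi1"),
      sc_row("CG2", "N", "CA", "CB", 1.527, 110.5, "chi1 - 120")),
    LEU = rbind(cb,
      sc_row("CG", "N", "CA", "CB", 1.530, 116.3, "chi1"),
      sc_row("CD1", "CA", "CB", "CG", 1.521, 110.7, "chi2"),
      sc_row("CD2", "CA", "CB", "CG", 1.521, 110.7, "chi2 + 120")),
    ILE = rbind(cb,
      sc_row("CG1", "N", "CA", "CB", 1.530, 110.4, "chi1"),
      sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1 - 120"),
      sc_row("CD1", "CA", "CB", "CG1", 1.513, 113.9, "chi2")),
    MET = rbind(cb,
      sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
      sc_row("SD", "CA", "CB", "CG", 1.803, 112.7, "chi2"),
      sc_row("CE", "CB", "CG", "SD", 1.791, 100.9, "chi3")),
    ASP = rbind(cb,
      sc_row("CG", "N", "CA", "CB", 1.516, 112.6, "chi1"),
      sc_row("OD1", "CA", "CB", "CG", 1.249, 118.4, "chi2"),
      sc_row("OD2", "CA", "CB", "CG", 1.249, 118.4, "chi2 + 180")),
    ASN = rbind(cb,
      sc_row("CG", "N", "CA", "CB", 1.516, 112.6, "chi1"),
      sc_row("OD1", "CA", "CB", "CG", 1.231, 120.8, "chi2"),
      sc_row("ND2", "CA", "CB", "CG", 1.328, 116.4, "chi2 + 180")),
    GLU = rbind(cb,
      sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
      sc_row("CD", "CA", "CB", "CG", 1.516, 112.6, "chi2"),
      sc_row("OE1", "CB", "CG", "CD", 1.249, 118.4, "chi3"),
      sc_row("OE2", "CB", "CG", "CD", 1.249, 118.4, "chi3 + 180")),
    GLN = rbind(cb,
      sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
      sc_row("CD", "CA", "CB", "CG", 1.516, 112.6, "chi2"),
      sc_row("OE1", "CB", "CG", "CD", 1.231, 120.8, "chi3"),
      sc_row("NE2", "CB", "CG", "CD", 1.328, 116.4, "chi3 + 180")),
    LYS = rbind(cb,
      sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
      sc_row("CD", "CA", "CB", "CG", 1.520, 111.3, "chi2"),
      sc_row("CE", "CB", "CG", "CD", 1.520, 111.3, "chi3"),
      sc_row("NZ", "CG", "CD", "CE", 1.489, 111.9, "chi4")),
    ARG = rbind(cb,
      sc_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
      sc_row("CD", "CA", "CB", "CG", 1.520, 111.3, "chi2"),
      sc_row("NE", "CB", "CG", "CD", 1.461, 112.0, "chi3"),
      sc_row("CZ", "CG", "CD", "NE", 1.329, 124.2, "chi4"),
      sc_row("NH1", "CD", "NE", "CZ", 1.326, 120.0, "0"),
      sc_row("NH2", "CD", "NE", "CZ", 1.326, 120.0, "180")),
    HIS = rbind(cb,
      sc_row("CG", "N", "CA", "CB", 1.497, 113.8, "chi1"),
      sc_row("ND1", "CA", "CB", "CG", 1.378, 122.7, "chi2"),
      sc_row("CD2", "ND1", "CB", "CG", 1.356, 131.1, "172.8"),
      sc_row("CE1", "CB", "CG", "ND1", 1.326, 109.2, "180"),
      sc_row("NE2", "CB", "CG", "CD2", 1.373, 107.2, "180")),
    PHE = rbind(cb, sc_row("CG", "N", "CA", "CB", 1.502, 113.8, "chi1"),
                ring6("CG")),
    TYR = rbind(cb, sc_row("CG", "N", "CA", "CB", 1.502, 113.8, "chi1"),
                ring6("CG"),
                sc_row("OH", "CD1", "CE1", "CZ", 1.376, 120.0, "180")),
    stop(sprintf("no side-chain template for residue '%s'", resname))
  )
}

# Default rotamer per residue: chi1 gauche- (-60), distal chis trans, except
# planar groups where chi2/chi3 of 90 keeps rings/carboxylates staggered.
default_chis <- function(resname) {
  chis <- c(chi1 = -60, chi2 = 180, chi3 = 180, chi4 = 180)
  if (resname %in% c("PHE", "TYR", "HIS")) chis["chi2"] <- 90
  if (resname %in% c("ASP", "ASN")) chis["chi2"] <- -20
  if (resname %in% c("GLU", "GLN")) chis["chi3"] <- -20
  chis
}

eval_tors <- function(tors, chis) {
  if (grepl("chi", tors)) {
    e <- parse(text = tors)[[1]]
    wrap_angle(eval(e, as.list(chis)))
  } else {
    as.numeric(tors)
  }
}

#' Build an ideal-geometry peptide at fixed backbone dihedrals
#'
#' Constructs a peptide chain from standard bond lengths and angles with all
#' residues at the given (phi, psi) and trans peptide bonds (omega = 180).
#' The alpha-helical default (-57, -47) gives consecutive Calpha-Calpha
#' distances of ~3.8 A. Side chains are built from idealised rotamer
#' templates for the 18 supported residue types.
#'
#' @param sequence one-letter amino-acid string (e.g. `"AALKEF"`).
#' @param phi,psi backbone dihedrals in degrees applied to every residue.
#' @param chain chain identifier.
#' @param first_resno residue number of the first residue.
#' @return an atom tibble.
#' @examples
#' h <- make_helix_domain("AALKA")
#' range(diff(which(h$name == "CA")))
#' @export
make_helix_domain <- function(sequence, phi = -57, psi = -47, chain = "A",
                              first_resno = 1L) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(letters1, names(AA_3LETTER))
  if (length(unknown) > 0)
    stop(sprintf("unsupported residue letter(s): %s",
                 paste(unique(unknown), collapse = ", ")))
  resnames <- unname(AA_3LETTER[letters1])
  nres <- length(resnames)

  rows <- list()
  add_atom <- function(name, resname, resno, pos, element = NULL) {
    rows[[length(rows) + 1]] <<- list(
      name = name, resname = resname, resno = resno,
      x = pos[1], y = pos[2], z = pos[3],
      element = element %||% guess_element(name))
  }

  prev <- NULL  # list(N, CA, C) of previous residue
  for (i in seq_len(nres)) {
    rn <- resnames[i]
    resno <- first_resno + i - 1L
    if (i == 1) {
      N <- c(0, 0, 0)
      CA <- c(BB$n_ca, 0, 0)
      th <- deg2rad(180 - BB$ang_n_ca_c)
      C <- CA + BB$ca_c * c(cos(th), sin(th), 0)
    } else {
      N <- place_atom(prev$N, prev$CA, prev$C, BB$c_n, BB$ang_ca_c_n, psi)
      CA <- place_atom(prev$CA, prev$C, N, BB$n_ca, BB$ang_c_n_ca, 180)
      C <- place_atom(prev$C, N, CA, BB$ca_c, BB$ang_n_ca_c, phi)
    }
    O <- place_atom(N, CA, C, BB$c_o, BB$ang_ca_c_o, wrap_angle(psi - 180))
    add_atom("N", rn, resno, N, "N")
    add_atom("CA", rn, resno, CA, "C")
    add_atom("C", rn, resno, C, "C")
    add_atom("O", rn, resno, O, "O")

    tpl <- sidechain_template(rn)
    if (!is.null(tpl)) {
      placed <- list(N = N, CA = CA, C = C, O = O)
      chis <- default_chis(rn)
      for (k in seq_len(nrow(tpl))) {
        pos <- place_atom(placed[[tpl$a[k]]], placed[[tpl$b[k]]],
                          placed[[tpl$c[k]]], tpl$length[k], tpl$angle[k],
                          eval_tors(tpl$tors[k], chis))
        placed[[tpl$name[k]]] <- pos
        add_atom(tpl$name[k], rn, resno, pos)
      }
    }
    prev <- list(N = N, CA = CA, C = C)
  }

  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  tibble::tibble(
    serial = seq_len(nrow(out)),
    name = out$name, altloc = "", resname = out$resname, chain = chain,
    resno = as.integer(out$resno), insert = "",
    x = out$x, y = out$y, z = out$z, occupancy = 1, element = out$element
  )
}

# Standard chi dihedral atom quadruples per residue type (chi1..chi4 where
# defined). Used both by torsion extraction and by set_chi1().
CHI_DEFS <- list(
  SER = list(c("N", "CA", "CB", "OG")),
  CYS = list(c("N", "CA", "CB", "SG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1"))
)

# Rotate the side chain of one residue about its CA-CB axis so that chi1
# equals `value` (degrees). All side-chain atoms beyond CB move rigidly.
set_chi1 <- function(structure, resno, value, chain = NULL) {
  sel <- structure$resno == resno &
    (if (is.null(chain)) TRUE else structure$chain == chain)
  res <- structure[sel, , drop = FALSE]
  if (nrow(res) == 0) stop(sprintf("residue %d not found", resno))
  defs <- CHI_DEFS[[res$resname[1]]]
  if (is.null(defs)) stop(sprintf("residue %s has no chi1", res$resname[1]))
  get <- function(nm) unlist(res[res$name == nm, c("x", "y", "z")])
  quad <- defs[[1]]
  cur <- dihedral(get(quad[1]), get(quad[2]), get(quad[3]), get(quad[4]))
  ca <- get("CA"); cb <- get("CB")
  R <- rotation_about_axis(cb - ca, value - cur)
  move <- sel & !(structure$name %in% c(BACKBONE_ATOMS, "CB"))
  xyz <- as.matrix(structure[move, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, cb) %*% t(R), 2, cb, `+`)
  structure[move, c("x", "y", "z")] <- as.data.frame(xyz)
  structure
}

#' Rigidly move a structure
#'
#' Applies rotation `R` (about the origin or about `center`) followed by
#' translation `t` to every atom.
#'
#' @param structure an atom tibble.
#' @param R 3x3 rotation matrix (default identity).
#' @param t translation 3-vector (default zero).
#' @param center optional 3-vector: rotate about this point instead of the
#'   origin.
#' @return the transformed structure.
#' @export
transform_structure <- function(structure, R = diag(3), t = c(0, 0, 0),
                                center = NULL) {
  xyz <- coords(structure)
  if (!is.null(center)) {
    xyz <- sweep(sweep(xyz, 2, center) %*% t(R), 2, center + t, `+`)
  } else {
    xyz <- sweep(xyz %*% t(R), 2, t, `+`)
  }
  set_coords(structure, xyz)
}
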