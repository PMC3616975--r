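# PDB ATOM-record reading and writing. A "structure" in this package is a
# tibble of heavy-atom records, one row per atom in file order, with columns
#   serial, name, altloc, resname, chain, resno, insert, x, y, z,
#   occupancy, element
# A conformational ensemble is a shared atom table plus an n_frames x 3N
# coordinate matrix (only positions differ between frames).

STRUCTURE_COLS <- c("serial", "name", "altloc", "resname", "chain", "resno",
                    "insert", "x", "y", "z", "occupancy", "element")

WATER_RESNAMES <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "DOD")

# Residue identity used throughout: "chain|resno|insert".
residue_key <- function(chain, resno, insert = "") {
  paste(chain, resno, ifelse(is.na(insert) | insert == " ", "", insert),
        sep = "|")
}

structure_residue_keys <- function(structure) {
  unique(residue_key(structure$chain, structure$resno, structure$insert))
}

assert_structure <- function(structure, arg = "structure") {
  if (!is.data.frame(structure) || !all(STRUCTURE_COLS %in% names(structure)))
    stop(sprintf("`%s` must be an atom tibble with columns %s", arg,
                 paste(STRUCTURE_COLS, collapse = ", ")), call. = FALSE)
  invisible(structure)
}

guess_element <- function(name) {
  two <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE")
  stripped <- gsub("[0-9' ]", "", name)
  first2 <- toupper(substr(stripped, 1, 2))
  ifelse(first2 %in% two, first2, toupper(substr(stripped, 1, 1)))
}

parse_atom_lines <- function(lines, line_numbers, path) {
  num_field <- function(txt, what) {
    out <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(out) | !is.finite(out))
    if (length(bad) > 0)
      stop(sprintf("malformed %s field in '%s' at line %d: '%s'",
                   what, path, line_numbers[bad[1]], trimws(txt[bad[1]])),
           call. = FALSE)
    out
  }
  pad <- function(l) formatC(l, width = 80, flag = "-")
  lines <- pad(lines)
  serial <- num_field(substr(lines, 7, 11), "serial")
  x <- num_field(substr(lines, 31, 38), "x-coordinate")
  y <- num_field(substr(lines, 39, 46), "y-coordinate")
  z <- num_field(substr(lines, 47, 54), "z-coordinate")
  occ_txt <- trimws(substr(lines, 55, 60))
  occ <- suppressWarnings(as.numeric(occ_txt))
  occ[is.na(occ)] <- 1
  name <- trimws(substr(lines, 13, 16))
  element <- trimws(substr(lines, 77, 78))
  element <- ifelse(element == "", guess_element(name), toupper(element))
  tibble::tibble(
    serial = as.integer(serial),
    name = name,
    altloc = substr(lines, 17, 17),
    resname = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    resno = as.integer(num_field(substr(lines, 23, 26), "residue number")),
    insert = trimws(substr(lines, 27, 27)),
    x = x, y = y, z = z,
    occupancy = occ,
    element = element
  )
}

# Altloc policy: keep the highest-occupancy conformer per (residue, atom
# name); ties resolved in favour of the first conformer encountered.
resolve_altloc <- function(atoms) {
  if (all(atoms$altloc %in% c(" ", ""))) {
    atoms$altloc <- ""
    return(atoms)
  }
  atoms$.row <- seq_len(nrow(atoms))
  kept <- atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$name) |>
    dplyr::slice_max(.data$occupancy, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row)
  kept$altloc <- ""
  kept$.row <- NULL
  kept
}

#' Read a single-model PDB structure
#'
#' Parses ATOM records (fixed-column PDB format) into an atom tibble.
#' Hydrogens, waters and (by default) HETATM records are dropped; alternate
#' conformers are reduced to the highest-occupancy copy.
#'
#' @param path path to a PDB file.
#' @param keep_hetatm also parse HETATM records (waters are still dropped).
#' @param keep_hydrogens keep hydrogen atoms; all metrics in this package
#'   follow the heavy-atom convention, so the default is `FALSE`.
#' @return an atom tibble (one row per atom, file order preserved).
#' @examples
#' helix <- make_helix_domain("AALKA")
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(helix, f)
#' read_pdb(f)
#' @export
read_pdb <- function(path, keep_hetatm = FALSE, keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep_rec <- rec == "ATOM  " | (keep_hetatm & rec == "HETATM")
  # Only the first model of a multi-model file.
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl) > 0) keep_rec[endmdl[1]:length(lines)] <- FALSE
  idx <- which(keep_rec)
  if (length(idx) == 0)
    stop(sprintf("no ATOM records found in '%s'", path), call. = FALSE)
  atoms <- parse_atom_lines(lines[idx], idx, path)
  atoms <- atoms[!(atoms$resname %in% WATER_RESNAMES), , drop = FALSE]
  if (!keep_hydrogens) atoms <- atoms[!(atoms$element %in% c("H", "D")), ,
                                      drop = FALSE]
  if (nrow(atoms) == 0)
    stop(sprintf("'%s' contains no usable heavy atoms", path), call. = FALSE)
  resolve_altloc(atoms)
}

format_atom_lines <- function(atoms) {
  name4 <- ifelse(nchar(atoms$name) >= 4 | nchar(atoms$element) == 2,
                  formatC(atoms$name, width = -4),
                  paste0(" ", formatC(atoms$name, width = -3)))
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial %% 100000L, name4, " ", atoms$resname,
          atoms$chain, atoms$resno,
          ifelse(atoms$insert == "", " ", atoms$insert),
          atoms$x, atoms$y, atoms$z, atoms$occupancy, 0, atoms$element)
}

#' Write a structure to a PDB file
#'
#' @param structure an atom tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  assert_structure(structure)
  writeLines(c(format_atom_lines(structure), "END"), path)
  invisible(path)
}

#' Construct an ensemble from an atom table and a frame matrix
#'
#' @param atoms atom tibble shared by every frame.
#' @param xyz n_frames x 3N coordinate matrix (each row is one frame's
#'   coordinates in x1, y1, z1, x2, ... order).
#' @return a `td_ensemble`.
#' @export
new_ensemble <- function(atoms, xyz) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3 * nrow(atoms))
  structure(
    list(atoms = atoms, xyz = xyz,
         topology_hash = paste(atoms$name, atoms$chain, atoms$resno,
                               collapse = ";")),
    class = "td_ensemble"
  )
}

#' @export
print.td_ensemble <- function(x, ...) {
  cat(sprintf("<td_ensemble> %d frames x %d atoms (%d residues)\n",
              nrow(x$xyz), nrow(x$atoms),
              length(structure_residue_keys(x$atoms))))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `td_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

#' Extract one frame of an ensemble as a structure
#' @param ensemble a `td_ensemble`.
#' @param i frame index (1-based).
#' @return an atom tibble with that frame's coordinates.
#' @export
frame_structure <- function(ensemble, i) {
  stopifnot(i >= 1, i <= n_frames(ensemble))
  set_coords(ensemble$atoms, matrix(ensemble$xyz[i, ], ncol = 3, byrow = TRUE))
}

#' Read a multi-model PDB file as a conformational ensemble
#'
#' One frame per MODEL/ENDMDL block (a file without MODEL records yields a
#' single-frame ensemble). All models must share the same atom count, atom
#' names and residue identities; only coordinates may differ.
#'
#' @inheritParams read_pdb
#' @return a `td_ensemble`.
#' @export
read_ensemble <- function(path, keep_hetatm = FALSE, keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  rec <- trimws(substr(lines, 1, 6))
  model_starts <- which(rec == "MODEL")
  if (length(model_starts) == 0) {
    s <- read_pdb(path, keep_hetatm, keep_hydrogens)
    return(new_ensemble(s, matrix(t(as.matrix(s[, c("x", "y", "z")])),
                                  nrow = 1)))
  }
  model_ends <- which(rec == "ENDMDL")
  if (length(model_ends) < length(model_starts))
    model_ends <- c(model_ends, length(lines))
  frames <- vector("list", length(model_starts))
  for (m in seq_along(model_starts)) {
    span <- (model_starts[m] + 1):(model_ends[m] - 1)
    keep <- rec[span] == "ATOM" | (keep_hetatm & rec[span] == "HETATM")
    idx <- span[keep]
    if (length(idx) == 0)
      stop(sprintf("model %d of '%s' contains no ATOM records", m, path),
           call. = FALSE)
    atoms <- parse_atom_lines(lines[idx], idx, path)
    atoms <- atoms[!(atoms$resname %in% WATER_RESNAMES), , drop = FALSE]
    if (!keep_hydrogens)
      atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
    frames[[m]] <- resolve_altloc(atoms)
  }
  ref <- frames[[1]]
  sig <- function(a) paste(a$name, a$chain, a$resno, a$insert, a$resname,
                           collapse = ";")
  ref_sig <- sig(ref)
  xyz <- matrix(NA_real_, nrow = length(frames), ncol = 3 * nrow(ref))
  for (m in seq_along(frames)) {
    fm <- frames[[m]]
    if (nrow(fm) != nrow(ref) || sig(fm) != ref_sig)
      stop(sprintf(
        "topology mismatch in '%s': model %d has %d atoms where model 1 has %d (atom names/residues must match)",
        path, m, nrow(fm), nrow(ref)), call. = FALSE)
    xyz[m, ] <- as.vector(t(as.matrix(fm[, c("x", "y", "z")])))
  }
  new_ensemble(ref, xyz)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble a `td_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "td_ensemble"))
  out <- character(0)
  for (i in seq_len(n_frames(ensemble))) {
    out <- c(out, sprintf("MODEL %8d", i),
             format_atom_lines(frame_structure(ensemble, i)), "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Coordinates of a structure as a matrix
#' @param structure an atom tibble.
#' @return n x 3 matrix of x, y, z.
#' @export
coords <- function(structure) {
  assert_structure(structure)
  as.matrix(structure[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param structure an atom tibble.
#' @param xyz n x 3 coordinate matrix.
#' @return the structure with new coordinates.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure), ncol(xyz) == 3)
  structure$x <- xyz[, 1]
  structure$y <- xyz[, 2]
  structure$z <- xyz[, 3]
  structure
}
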