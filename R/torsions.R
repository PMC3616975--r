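# Torsion-angle extraction over conformational ensembles: backbone phi, psi
# and omega plus side-chain chi1-chi4 where defined. One series per torsion
# per residue, length = number of frames.

BACKBONE_TORSIONS <- c("phi", "psi", "omega")

#' Extract per-residue torsion series from an ensemble
#'
#' Computes backbone (phi, psi, omega) and side-chain (chi1..chi4) dihedral
#' angles for every residue across every frame. Terminal residues lack phi
#' (first) and psi/omega (psi of the last residue and omega of the first
#' need atoms from a neighbour). Torsions whose defining atoms are missing
#' are omitted with a single summary warning rather than an error.
#'
#' @param ensemble a `td_ensemble` (or an atom tibble, treated as one frame).
#' @param torsions which torsion types to extract.
#' @return a tibble with columns chain, resno, resname, residue (key),
#'   torsion, and a list-column `angles` (degrees in \[-180, 180), one value
#'   per frame).
#' @export
extract_torsions <- function(ensemble,
                             torsions = c("phi", "psi", "omega",
                                          paste0("chi", 1:4))) {
  if (is.data.frame(ensemble)) {
    s <- ensemble
    ensemble <- new_ensemble(s, matrix(as.vector(t(coords(s))), nrow = 1))
  }
  atoms <- ensemble$atoms
  xyz <- ensemble$xyz

  res <- atoms |>
    dplyr::distinct(.data$chain, .data$resno, .data$insert, .data$resname)
  idx_of <- function(chain, resno, insert, name) {
    i <- which(atoms$chain == chain & atoms$resno == resno &
                 atoms$insert == insert & atoms$name == name)
    if (length(i) == 0) NA_integer_ else i[1]
  }

  out <- list()
  missing_log <- character(0)
  for (r in seq_len(nrow(res))) {
    ch <- res$chain[r]; rn <- res$resno[r]; ins <- res$insert[r]
    same_chain_prev <- r > 1 && res$chain[r - 1] == ch &&
      res$resno[r - 1] == rn - 1
    same_chain_next <- r < nrow(res) && res$chain[r + 1] == ch &&
      res$resno[r + 1] == rn + 1
    get4 <- function(spec) {
      # spec: list of c(resno_offset, atom_name)
      v <- vapply(spec, function(s) {
        idx_of(ch, rn + as.integer(s[1]), ins, s[2])
      }, integer(1))
      if (anyNA(v)) NULL else v
    }
    defs <- list()
    if ("phi" %in% torsions && same_chain_prev)
      defs$phi <- list(c(-1, "C"), c(0, "N"), c(0, "CA"), c(0, "C"))
    if ("psi" %in% torsions && same_chain_next)
      defs$psi <- list(c(0, "N"), c(0, "CA"), c(0, "C"), c(1, "N"))
    if ("omega" %in% torsions && same_chain_prev)
      defs$omega <- list(c(-1, "CA"), c(-1, "C"), c(0, "N"), c(0, "CA"))
    chis <- CHI_DEFS[[res$resname[r]]]
    if (!is.null(chis)) {
      for (k in seq_along(chis)) {
        lab <- paste0("chi", k)
        if (lab %in% torsions)
          defs[[lab]] <- lapply(chis[[k]], function(nm) c(0, nm))
      }
    }
    for (lab in names(defs)) {
      q <- get4(defs[[lab]])
      if (is.null(q)) {
        missing_log <- c(missing_log,
                         sprintf("%s %s%d", lab, ch, rn))
        next
      }
      out[[length(out) + 1]] <- tibble::tibble(
        chain = ch, resno = rn, resname = res$resname[r],
        residue = residue_key(ch, rn, ins), torsion = lab,
        angles = list(dihedral_series(xyz, q[1], q[2], q[3], q[4]))
      )
    }
  }
  if (length(missing_log) > 0)
    warning(sprintf("omitted %d torsion(s) with missing atoms: %s",
                    length(missing_log),
                    paste(utils::head(missing_log, 5), collapse = ", ")),
            call. = FALSE)
  if (length(out) == 0)
    stop("no torsions could be extracted", call. = FALSE)
  dplyr::bind_rows(out)
}
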