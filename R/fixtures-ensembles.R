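# Deterministic ensemble generators: jittered rigid bodies for RMSF/RMSD
# tests and coupled-rotamer ensembles that plant known statistical coupling
# between side-chain chi1 states.

#' Gaussian-jitter ensemble around a structure
#'
#' Frame k is the input structure plus independent per-coordinate Gaussian
#' noise. The noise SD can vary per residue (e.g. zero on a fit region so
#' superposition is exact); an isotropic per-coordinate SD of sigma gives an
#' expected per-atom RMSF of sigma * sqrt(3).
#'
#' @param structure an atom tibble.
#' @param sigma either a single SD (angstroms) applied to every atom or a
#'   named vector `sigma[resno]` per residue number (unlisted residues get 0).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return a `td_ensemble`.
#' @export
make_jitter_ensemble <- function(structure, sigma, n_frames, seed) {
  assert_structure(structure)
  stopifnot(n_frames >= 1, all(sigma >= 0))
  set.seed(seed)
  if (is.null(names(sigma))) {
    atom_sd <- rep(sigma[1], nrow(structure))
  } else {
    atom_sd <- unname(sigma[as.character(structure$resno)])
    atom_sd[is.na(atom_sd)] <- 0
  }
  base <- as.vector(t(coords(structure)))
  sd_flat <- rep(atom_sd, each = 3)
  xyz <- matrix(0, nrow = n_frames, ncol = length(base))
  for (k in seq_len(n_frames)) {
    xyz[k, ] <- base + stats::rnorm(length(base), sd = sd_flat)
  }
  new_ensemble(structure, xyz)
}

# Sample paired two-state indicators from a 2x2 joint probability table.
sample_joint_states <- function(joint, n) {
  joint <- as.matrix(joint)
  if (!all(dim(joint) == c(2, 2)) || any(joint < 0) ||
      abs(sum(joint) - 1) > 1e-8)
    stop("joint table must be 2x2 with non-negative entries summing to 1")
  cell <- sample.int(4, n, replace = TRUE, prob = as.vector(joint))
  # as.vector is column-major: cell 1=(1,1), 2=(2,1), 3=(1,2), 4=(2,2)
  list(a = ifelse(cell %in% c(1, 3), 1L, 2L),
       b = ifelse(cell %in% c(1, 2), 1L, 2L))
}

#' Coupled-rotamer ensemble with planted chi1 coupling
#'
#' Builds a poly-LEU helix (side chains carry a well-defined chi1) and an
#' ensemble in which each residue's chi1 jumps between two rotamer wells,
#' gauche- (-60) and trans (180). Listed residue pairs draw their joint well
#' occupancy from a user 2x2 probability table; all other residues flip
#' independently (50/50). Wells carry Gaussian within-well noise of 5
#' degrees, so a 15-degree binning separates them cleanly.
#'
#' @param n_residues helix length (all LEU).
#' @param coupled_pairs list of entries `list(i =, j =, joint = 2x2 matrix)`
#'   with `i`, `j` residue numbers (1-based).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param well_sd within-well Gaussian noise SD, degrees.
#' @return a `td_ensemble`; the planted truth is attached as attribute
#'   `"planted"` (tibble of coupled residue-number pairs).
#' @export
make_rotamer_ensemble <- function(n_residues, coupled_pairs = list(),
                                  n_frames, seed, well_sd = 5) {
  stopifnot(n_residues >= 2, n_frames >= 1)
  set.seed(seed)
  base <- make_helix_domain(strrep("L", n_residues))
  wells <- c(-60, 180)

  states <- matrix(0L, nrow = n_frames, ncol = n_residues)
  coupled_res <- integer(0)
  for (cp in coupled_pairs) {
    st <- sample_joint_states(cp$joint, n_frames)
    states[, cp$i] <- st$a
    states[, cp$j] <- st$b
    coupled_res <- c(coupled_res, cp$i, cp$j)
  }
  free <- setdiff(seq_len(n_residues), coupled_res)
  for (r in free) states[, r] <- sample.int(2, n_frames, replace = TRUE)

  chi <- matrix(wells[states], nrow = n_frames) +
    matrix(stats::rnorm(n_frames * n_residues, sd = well_sd),
           nrow = n_frames)

  xyz <- matrix(0, nrow = n_frames, ncol = 3 * nrow(base))
  for (k in seq_len(n_frames)) {
    s <- base
    for (r in seq_len(n_residues)) s <- set_chi1(s, r, chi[k, r])
    xyz[k, ] <- as.vector(t(coords(s)))
  }
  ens <- new_ensemble(base, xyz)
  attr(ens, "planted") <- dplyr::bind_rows(lapply(coupled_pairs, function(cp)
    tibble::tibble(res_i = cp$i, res_j = cp$j)))
  ens
}
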