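# Stability analytics over conformational ensembles: superposition-based
# RMSF profiles, per-frame segment RMSD series, distance monitors, and the
# assembly of the per-model ranking table.

ens_xyz_frame <- function(ensemble, i) {
  matrix(ensemble$xyz[i, ], ncol = 3, byrow = TRUE)
}

fit_indices <- function(ensemble, domain, atoms) {
  which(selection_mask(ensemble$atoms, domain, atoms, NULL, NULL))
}

#' Superpose every frame of an ensemble onto a reference frame
#'
#' Kabsch-fits each frame onto `ref_frame` over the fit selection (e.g. the
#' static/kinase domain Calpha atoms); the fitted transform is applied to
#' the whole frame.
#'
#' @param ensemble a `td_ensemble`.
#' @param fit_domain [domain_def()] row(s) defining the fit region (NULL =
#'   whole structure).
#' @param atoms atom names used in the fit (default CA).
#' @param ref_frame reference frame index.
#' @return the fitted `td_ensemble`.
#' @export
superpose_ensemble <- function(ensemble, fit_domain = NULL, atoms = "CA",
                               ref_frame = 1) {
  idx <- fit_indices(ensemble, fit_domain, atoms)
  if (length(idx) < 3) stop("fit selection has fewer than 3 atoms")
  ref <- ens_xyz_frame(ensemble, ref_frame)[idx, , drop = FALSE]
  out <- ensemble$xyz
  for (i in seq_len(n_frames(ensemble))) {
    fr <- ens_xyz_frame(ensemble, i)
    fit <- kabsch(fr[idx, , drop = FALSE], ref)
    out[i, ] <- as.vector(t(apply_fit(fr, fit)))
  }
  new_ensemble(ensemble$atoms, out)
}

#' Root-mean-square fluctuation profile
#'
#' Per-residue Calpha RMSF about the time-mean position after superposing
#' every frame on the fit region: the published panel's PK_RMSF is the mean
#' RMSF of the mobile (pseudokinase) domain after fitting on the kinase
#' domain, and KH_RMSF the same quantity measured over the kinase alpha-C
#' helix.
#'
#' @param ensemble a `td_ensemble` with >= 2 frames.
#' @param fit_domain fit region (see [superpose_ensemble()]).
#' @param measure_domain [domain_def()] row(s) to profile.
#' @param atoms atom names measured (default CA).
#' @return a `td_rmsf`: tibble(chain, resno, residue, rmsf) with the mean
#'   over the selection in `glance()`/attribute `mean_rmsf`.
#' @export
rmsf <- function(ensemble, fit_domain = NULL, measure_domain = NULL,
                 atoms = "CA") {
  if (n_frames(ensemble) < 2)
    stop("RMSF needs at least 2 frames", call. = FALSE)
  fitted <- superpose_ensemble(ensemble, fit_domain, atoms)
  midx <- fit_indices(fitted, measure_domain, atoms)
  if (length(midx) == 0) stop("empty measure selection")
  cols <- as.vector(rbind(3 * midx - 2, 3 * midx - 1, 3 * midx))
  sub <- fitted$xyz[, cols, drop = FALSE]
  mean_pos <- colMeans(sub)
  dev2 <- sweep(sub, 2, mean_pos)^2
  # per-atom fluctuation: sqrt(mean over frames of squared 3D deviation)
  per_atom <- sqrt(rowSums(matrix(colMeans(dev2), ncol = 3, byrow = TRUE)))
  atoms_tbl <- fitted$atoms[midx, , drop = FALSE]
  prof <- tibble::tibble(
    chain = atoms_tbl$chain, resno = atoms_tbl$resno,
    residue = residue_key(atoms_tbl$chain, atoms_tbl$resno,
                          atoms_tbl$insert),
    rmsf = per_atom)
  structure(prof, class = c("td_rmsf", class(prof)),
            mean_rmsf = mean(per_atom))
}

#' @export
glance.td_rmsf <- function(x, ...) {
  tibble::tibble(n_atoms = nrow(x), mean_rmsf = attr(x, "mean_rmsf"),
                 max_rmsf = max(x$rmsf))
}

#' Mean RMSF over a selection
#' @param x a `td_rmsf` profile.
#' @return mean RMSF in angstroms.
#' @export
mean_rmsf <- function(x) attr(x, "mean_rmsf")

#' Per-frame segment RMSD series
#'
#' RMSD of the measure selection's Calpha atoms in each frame relative to a
#' reference structure, after fitting the frame onto the reference over the
#' fit selection (monitors e.g. activation-loop displacement while the
#' kinase core is held fixed).
#'
#' @param ensemble a `td_ensemble`.
#' @param reference atom tibble sharing the ensemble topology (defaults to
#'   frame 1).
#' @param fit_domain,measure_domain fit and measure regions.
#' @param atoms atom names (default CA).
#' @return a `td_series` tibble: frame, value (A), label.
#' @export
segment_rmsd_series <- function(ensemble, reference = NULL,
                                fit_domain = NULL, measure_domain = NULL,
                                atoms = "CA") {
  fidx <- fit_indices(ensemble, fit_domain, atoms)
  midx <- fit_indices(ensemble, measure_domain, atoms)
  if (length(fidx) < 3) stop("fit selection has fewer than 3 atoms")
  if (length(midx) == 0) stop("empty measure selection")
  ref_xyz <- if (is.null(reference)) ens_xyz_frame(ensemble, 1) else {
    if (nrow(reference) != nrow(ensemble$atoms))
      stop("reference does not share the ensemble topology")
    coords(reference)
  }
  vals <- vapply(seq_len(n_frames(ensemble)), function(i) {
    fr <- ens_xyz_frame(ensemble, i)
    fit <- kabsch(fr[fidx, , drop = FALSE], ref_xyz[fidx, , drop = FALSE])
    fr_fit <- apply_fit(fr[midx, , drop = FALSE], fit)
    sqrt(mean(rowSums((fr_fit - ref_xyz[midx, , drop = FALSE])^2)))
  }, numeric(1))
  new_series(vals, "segment RMSD (A)")
}

new_series <- function(values, label) {
  out <- tibble::tibble(frame = seq_along(values), value = values,
                        label = label)
  structure(out, class = c("td_series", class(out)))
}

#' Per-frame distance monitor between two atom groups
#'
#' Modes: `"centroid"` (unweighted centroid of each group's selected heavy
#' atoms — pass ring atom names to monitor aromatic stacking), `"min"`
#' (closest approach) or `"CA"` (Calpha-Calpha; groups must then be single
#' residues).
#'
#' @param ensemble a `td_ensemble`.
#' @param group_a,group_b selection lists passed to [select_atoms()], e.g.
#'   `list(resno = 595)` or `list(resno = 617, atoms = c("CG","CD1",...))`.
#' @param mode distance mode.
#' @return a `td_series` tibble: frame, value (A), label.
#' @export
distance_series <- function(ensemble, group_a, group_b,
                            mode = c("centroid", "min", "CA")) {
  mode <- match.arg(mode)
  sel <- function(g) {
    if (mode == "CA") g$atoms <- "CA"
    which(selection_mask(ensemble$atoms, g$domain %||% NULL,
                         g$atoms %||% NULL, g$resno %||% NULL,
                         g$chain %||% NULL))
  }
  ia <- sel(group_a); ib <- sel(group_b)
  if (length(ia) == 0 || length(ib) == 0) stop("empty group selection")
  vals <- vapply(seq_len(n_frames(ensemble)), function(i) {
    fr <- ens_xyz_frame(ensemble, i)
    a <- fr[ia, , drop = FALSE]; b <- fr[ib, , drop = FALSE]
    if (mode == "min") min_interdomain_distance(a, b)
    else vnorm(colMeans(a) - colMeans(b))
  }, numeric(1))
  new_series(vals, sprintf("%s distance (A)", mode))
}

round_half_up <- function(x) floor(x + 0.5)

#' Per-model ranking table (interface metric panel)
#'
#' Evaluates the metric panel for each model over its ensemble: mean and SD
#' of the interdomain interaction energy across frames, PK_RMSF (mobile
#' domain Calpha RMSF after fitting on the static domain), time-averaged
#' BSA, time-averaged contact counts (ionic/hydrophobic, rounded half-up to
#' integers), and KH_RMSF (static-domain helix RMSF) when a helix range is
#' given. Rows are sorted by mean binding energy, most favourable first.
#'
#' @param models list of model entries: `list(label =, ensemble =,
#'   static = domain_def, mobile = domain_def, helix = domain_def or NULL)`.
#' @param params a [nonbonded_params()].
#' @param hydrophobic_cutoff,ionic_cutoff contact cutoffs, A.
#' @param probe,n_points SASA settings.
#' @return a `td_ranking` tibble: model, e_bind_mean, e_bind_sd, pk_rmsf,
#'   bsa, n_ionic, n_hydrophobic, contacts ("ionic/hydrophobic"), kh_rmsf.
#' @export
ranking_table <- function(models, params = nonbonded_params(),
                          hydrophobic_cutoff = 5, ionic_cutoff = 6,
                          probe = 1.4, n_points = 960) {
  stopifnot(length(models) >= 1)
  rows <- lapply(models, function(m) {
    ens <- m$ensemble
    per_frame <- lapply(seq_len(n_frames(ens)), function(i) {
      s <- frame_structure(ens, i)
      e <- interaction_energy(s, m$static, m$mobile, params)
      tibble::tibble(
        e_bind = e$e_bind,
        bsa = buried_surface_area(s, m$static, m$mobile, probe, n_points),
        n_ionic = nrow(ionic_contacts(s, m$static, m$mobile, ionic_cutoff)),
        n_hydrophobic = nrow(hydrophobic_contacts(s, m$static, m$mobile,
                                                  hydrophobic_cutoff)))
    }) |> dplyr::bind_rows()
    pk <- if (n_frames(ens) >= 2)
      mean_rmsf(rmsf(ens, fit_domain = m$static, measure_domain = m$mobile))
    else 0
    kh <- if (!is.null(m$helix) && n_frames(ens) >= 2)
      mean_rmsf(rmsf(ens, fit_domain = m$static, measure_domain = m$helix))
    else NA_real_
    n_i <- round_half_up(mean(per_frame$n_ionic))
    n_h <- round_half_up(mean(per_frame$n_hydrophobic))
    tibble::tibble(
      model = m$label,
      e_bind_mean = mean(per_frame$e_bind),
      e_bind_sd = if (nrow(per_frame) > 1) stats::sd(per_frame$e_bind) else 0,
      pk_rmsf = pk,
      bsa = mean(per_frame$bsa),
      n_ionic = n_i, n_hydrophobic = n_h,
      contacts = sprintf("%d/%d", n_i, n_h),
      kh_rmsf = kh)
  })
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$e_bind_mean)
  structure(out, class = c("td_ranking", class(out)))
}

#' Write a ranking table as TSV with panel-style headers
#'
#' @param ranking a `td_ranking` from [ranking_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path) {
  out <- tibble::tibble(
    "Type" = ranking$model,
    "Interaction Energy (kcal/mol)" = sprintf("%.1f+/-%.1f",
                                              ranking$e_bind_mean,
                                              ranking$e_bind_sd),
    "PK_RMSF (A)" = sprintf("%.1f", ranking$pk_rmsf),
    "BSA(A^2)" = sprintf("%.0f", ranking$bsa),
    "Contacts" = ranking$contacts,
    "KH_RMSF (A)" = ifelse(is.na(ranking$kh_rmsf), "",
                           sprintf("%.1f", ranking$kh_rmsf)))
  readr::write_tsv(out, path)
  invisible(path)
}
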