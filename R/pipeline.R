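# Pipeline orchestration: couple -> dock -> triage, with a validated
# config, per-stage run logs and deterministic seeding. Each stage is a
# thin wrapper over the module functions so running stages separately
# equals the end-to-end run.

#' Pipeline configuration
#'
#' Collects every tunable of the workflow with the published defaults:
#' coupling (24 torsion bins, 100 permutations), sampler (8 deg / 8 deg /
#' 3 A / 8 A Gaussian SDs, 10,000 poses), tether cutoff 60 A, top 5
#' clusters, contact cutoffs 5 A (hydrophobic) and 6 A (ionic), stacking
#' window 4.5-7.0 A, SASA probe 1.4 A.
#'
#' @param seed RNG seed used by every stochastic stage.
#' @param n_bins,n_permutations,min_coupling coupling-stage settings.
#' @param sampler a [perturbation_spec()].
#' @param n_poses number of sampled poses.
#' @param tether a [tether_spec()] or NULL.
#' @param top_k clusters carried forward.
#' @param contact_gap seed-placement contact gap, A.
#' @param hydrophobic_cutoff,ionic_cutoff,stacking_range,probe,n_points
#'   metric settings.
#' @param clash_min_dist,clash_max_violations clash-screen settings.
#' @param strict_clash drop (rather than only flag) clashing poses.
#' @param out_dir optional output directory for stage TSVs and run logs.
#' @return a validated `td_config` list.
#' @export
pipeline_config <- function(seed = 1, n_bins = 24, n_permutations = 100,
                            min_coupling = 0.1,
                            sampler = perturbation_spec(), n_poses = 10000,
                            tether = NULL, top_k = 5, contact_gap = 4,
                            hydrophobic_cutoff = 5, ionic_cutoff = 6,
                            stacking_range = c(4.5, 7.0), probe = 1.4,
                            n_points = 960, clash_min_dist = 2.5,
                            clash_max_violations = 5, strict_clash = FALSE,
                            out_dir = NULL) {
  stopifnot(n_bins > 1, n_permutations >= 50, n_poses >= 1, top_k >= 1,
            hydrophobic_cutoff > 0, ionic_cutoff > 0, probe > 0,
            all(stacking_range > 0), contact_gap > 0, clash_min_dist > 0)
  structure(as.list(environment()), class = "td_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()] arguments; `sampler` and
#' `tether` are nested mappings, `domains` an optional list of
#' label/chain/first/last entries returned alongside the config.
#'
#' @param path YAML file.
#' @return list with `config` (a `td_config`) and `domains` (tibble or NULL).
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  domains <- NULL
  if (!is.null(raw$domains)) {
    domains <- dplyr::bind_rows(lapply(raw$domains, function(d)
      domain_def(d$label, d$chain, d$first, d$last)))
    raw$domains <- NULL
  }
  if (!is.null(raw$sampler)) raw$sampler <- do.call(perturbation_spec,
                                                    raw$sampler)
  if (!is.null(raw$tether)) raw$tether <- do.call(tether_spec, raw$tether)
  list(config = do.call(pipeline_config, raw), domains = domains)
}

log_stage <- function(config, stage, lines) {
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    cat(sprintf("[%s] %s\n", stage, lines), sep = "",
        file = file.path(config$out_dir, "run_log.txt"), append = TRUE)
  }
  invisible(NULL)
}

#' Coupling stage: torsion MI matrix and site groups
#'
#' @param ensembles a `td_ensemble` or list of topology-matched ensembles
#'   (frames pooled).
#' @param config a [pipeline_config()].
#' @return list with `matrix` (`td_coupling`) and `sites` (tibble).
#' @export
run_couple <- function(ensembles, config = pipeline_config()) {
  ens <- pool_ensembles(ensembles)
  torsions <- extract_torsions(ens)
  cm <- residue_coupling_matrix(torsions, n_bins = config$n_bins,
                                n_permutations = config$n_permutations,
                                seed = config$seed)
  sites <- cluster_sites(cm, min_coupling = config$min_coupling)
  log_stage(config, "couple",
            sprintf("frames=%d residues=%d significant_pairs=%d sites=%d seed=%d",
                    n_frames(ens), length(cm$residues),
                    sum(cm$mask[upper.tri(cm$mask)]), nrow(sites),
                    config$seed))
  if (!is.null(config$out_dir)) {
    utils::write.table(cm$values,
                       file.path(config$out_dir, "coupling_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    export_network(cm, file.path(config$out_dir, "coupling_network.tsv"))
    yaml::write_yaml(
      lapply(seq_len(nrow(sites)), function(i) list(
        label = sites$label[i], residues = sites$residues[[i]],
        mean_internal_coupling = sites$mean_internal_coupling[i])),
      file.path(config$out_dir, "site_groups.yaml"))
  }
  list(matrix = cm, sites = sites)
}

#' Docking stage: seed placement and Gaussian pose sampling
#'
#' @param static,mobile the two domains (reference frames).
#' @param site_static,site_mobile nominated site residue numbers (used for
#'   seed placement); alternatively pass an explicit `seed_pose`.
#' @param config a [pipeline_config()].
#' @param seed_pose optional pre-built seed pose (skips placement).
#' @return pose manifest tibble with clash annotations; the seed pose is
#'   attached as attribute `"seed_pose"`.
#' @export
run_dock <- function(static, mobile, site_static = NULL, site_mobile = NULL,
                     config = pipeline_config(), seed_pose = NULL) {
  if (is.null(seed_pose)) {
    if (is.null(site_static) || is.null(site_mobile))
      stop("supply site residues or an explicit seed_pose")
    seed_pose <- seed_placement(static, mobile, site_static, site_mobile,
                                contact_gap = config$contact_gap)
  }
  poses <- sample_poses(seed_pose, config$sampler, config$n_poses,
                        seed = config$seed, static = static,
                        mobile = mobile)
  poses <- clash_screen(poses, static, mobile, config$clash_min_dist,
                        config$clash_max_violations)
  log_stage(config, "dock",
            sprintf("poses=%d clash_flagged=%d seed=%d", nrow(poses),
                    sum(!poses$clash_ok), config$seed))
  if (!is.null(config$out_dir))
    write_pose_manifest(poses, file.path(config$out_dir,
                                         "pose_manifest.tsv"))
  attr(poses, "seed_pose") <- seed_pose
  poses
}

#' Triage stage: tether filter, clustering, representatives, metric panel
#'
#' @param poses pose manifest from [run_dock()].
#' @param static,mobile the two domains (reference frames).
#' @param tether a [tether_spec()] (overrides `config$tether`).
#' @param config a [pipeline_config()].
#' @return list: `filtered` (surviving manifest), `clusters` (`td_clust`),
#'   `top` (top-cluster summary), `reports` (per-representative
#'   `tidy()`'d interface metrics + energy), `counts` (stage count tibble).
#' @export
run_triage <- function(poses, static, mobile, tether = NULL,
                       config = pipeline_config()) {
  tether <- tether %||% config$tether
  if (is.null(tether)) stop("a tether_spec is required for triage")
  if (isTRUE(config$strict_clash) && "clash_ok" %in% names(poses))
    poses <- poses[poses$clash_ok, , drop = FALSE]
  filtered <- filter_by_tether(poses, static, mobile, tether)
  rep_t <- tether_report(filtered)
  counts <- tibble::tibble(stage = "tether", n = nrow(filtered))
  if (nrow(filtered) == 0) {
    log_stage(config, "triage", "no poses survive the tether filter")
    return(list(filtered = filtered, clusters = NULL, top = NULL,
                reports = NULL, counts = counts))
  }
  if (nrow(filtered) == 1) {
    top <- tibble::tibble(cluster = 1L, size = 1L, spread = 0,
                          representative = filtered$id[1])
    clusters <- NULL
  } else {
    dm <- pairwise_pose_rmsd(filtered, static, mobile)
    clusters <- nmrclust(dm)
    top <- top_clusters(clusters,
                        k = min(config$top_k,
                                length(unique(clusters$labels$cluster))))
  }
  reports <- lapply(top$representative, function(pid) {
    posed <- apply_pose(mobile, filtered[filtered$id == pid, ])
    cx <- dplyr::bind_rows(static, posed)
    cx$serial <- seq_len(nrow(cx))
    def_s <- domain_def("static", static$chain[1], min(static$resno),
                        max(static$resno))
    def_m <- domain_def("mobile", posed$chain[1], min(posed$resno),
                        max(posed$resno))
    dplyr::bind_cols(
      tibble::tibble(pose_id = pid),
      tidy(interface_report(cx, def_s, def_m,
                            hydrophobic_cutoff = config$hydrophobic_cutoff,
                            ionic_cutoff = config$ionic_cutoff,
                            stacking_range = config$stacking_range,
                            probe = config$probe,
                            n_points = config$n_points)),
      interaction_energy(cx, def_s, def_m))
  }) |> dplyr::bind_rows()
  counts <- dplyr::bind_rows(
    tibble::tibble(stage = "input", n = rep_t$n_in),
    tibble::tibble(stage = "tether", n = rep_t$n_kept),
    tibble::tibble(stage = "clusters",
                   n = if (is.null(clusters)) 1L else
                     length(unique(clusters$labels$cluster))),
    tibble::tibble(stage = "representatives", n = nrow(top)))
  log_stage(config, "triage",
            paste(sprintf("%s=%d", counts$stage, counts$n), collapse = " "))
  if (!is.null(config$out_dir)) {
    write_pose_manifest(filtered, file.path(config$out_dir,
                                            "filtered_manifest.tsv"))
    if (!is.null(clusters)) {
      readr::write_tsv(clusters$labels,
                       file.path(config$out_dir, "cluster_labels.tsv"))
      readr::write_tsv(clusters$penalty_trace,
                       file.path(config$out_dir, "penalty_trace.tsv"))
    }
    readr::write_tsv(reports, file.path(config$out_dir,
                                        "representative_reports.tsv"))
  }
  list(filtered = filtered, clusters = clusters, top = top,
       reports = reports, counts = counts)
}

#' Ranking stage: metric panel over the representative poses
#'
#' Builds each representative's complex (optionally as a jittered
#' mini-ensemble for fluctuation columns; by default single conformations,
#' so SD and RMSF columns are zero) and assembles the ranking table.
#'
#' @param triage result list from [run_triage()].
#' @param static,mobile the two domains (reference frames).
#' @param config a [pipeline_config()].
#' @param helix optional [domain_def()] for the KH_RMSF column.
#' @return a `td_ranking` tibble (written as `ranking.tsv` when the config
#'   has an `out_dir`).
#' @export
run_rank <- function(triage, static, mobile, config = pipeline_config(),
                     helix = NULL) {
  if (is.null(triage$top) || nrow(triage$top) == 0)
    stop("triage produced no representatives to rank")
  def_s <- domain_def("static", static$chain[1], min(static$resno),
                      max(static$resno))
  def_m <- domain_def("mobile", mobile$chain[1], min(mobile$resno),
                      max(mobile$resno))
  models <- lapply(seq_len(nrow(triage$top)), function(i) {
    pid <- triage$top$representative[i]
    posed <- apply_pose(mobile, triage$filtered[triage$filtered$id == pid, ])
    cx <- dplyr::bind_rows(static, posed)
    cx$serial <- seq_len(nrow(cx))
    list(label = sprintf("cluster%d_pose%d", triage$top$cluster[i], pid),
         ensemble = new_ensemble(cx, matrix(as.vector(t(coords(cx))),
                                            nrow = 1)),
         static = def_s, mobile = def_m, helix = helix)
  })
  ranking <- ranking_table(models,
                           hydrophobic_cutoff = config$hydrophobic_cutoff,
                           ionic_cutoff = config$ionic_cutoff,
                           probe = config$probe, n_points = config$n_points)
  log_stage(config, "rank", sprintf("models=%d best=%s", nrow(ranking),
                                    ranking$model[1]))
  if (!is.null(config$out_dir))
    write_ranking_tsv(ranking, file.path(config$out_dir, "ranking.tsv"))
  ranking
}
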