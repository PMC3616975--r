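# Pose clustering by tethered RMSD with an NMRCLUST-style stopping rule.
#
# The pose-comparison metric superposes one complex onto the other over the
# static domain's Calpha atoms (Kabsch) and then takes the plain Calpha RMSD
# of the mobile domain — the "tethered RMSD". Average-linkage agglomeration
# is cut at the step minimising the sum of two terms, the average
# intra-cluster spread and the cluster count, each linearly normalised onto
# [1, n_steps]; cluster representatives are medoids.

#' Tethered RMSD between two posed complexes
#'
#' @param complex_i,complex_j atom tibbles of the full two-domain complex in
#'   the two poses (same topology).
#' @param static_domain,mobile_domain [domain_def()] rows naming the fit and
#'   measure regions.
#' @param atoms atom name(s) used for both fit and measure (default CA).
#' @return RMSD in angstroms.
#' @export
tethered_rmsd <- function(complex_i, complex_j, static_domain, mobile_domain,
                          atoms = "CA") {
  si <- coords(select_atoms(complex_i, domain = static_domain, atoms = atoms))
  sj <- coords(select_atoms(complex_j, domain = static_domain, atoms = atoms))
  mi <- coords(select_atoms(complex_i, domain = mobile_domain, atoms = atoms))
  mj <- coords(select_atoms(complex_j, domain = mobile_domain, atoms = atoms))
  tethered_rmsd_xyz(si, mi, sj, mj)
}

tethered_rmsd_xyz <- function(static_i, mobile_i, static_j, mobile_j) {
  if (nrow(static_i) < 3)
    stop("need at least 3 static-domain atoms for superposition")
  fit <- kabsch(static_j, static_i)
  mobile_j_fit <- apply_fit(mobile_j, fit)
  sqrt(mean(rowSums((mobile_i - mobile_j_fit)^2)))
}

#' Pairwise tethered-RMSD matrix over a pose manifest
#'
#' @param poses pose manifest tibble (>= 2 rows).
#' @param static,mobile the two domains (reference frames).
#' @param atoms atom name(s) for fit and measure selections.
#' @return a `td_pose_dist`: list with `ids` and the symmetric `values`
#'   matrix (A, zero diagonal).
#' @export
pairwise_pose_rmsd <- function(poses, static, mobile, atoms = "CA") {
  n <- nrow(poses)
  if (n < 2) stop("need at least 2 poses")
  xyz_s <- coords(select_atoms(static, atoms = atoms))
  xyz_m0 <- coords(select_atoms(mobile, atoms = atoms))
  posed <- lapply(seq_len(n), function(k) {
    tr <- pose_transform(poses[k, ])
    sweep(xyz_m0 %*% t(tr$R), 2, tr$t, `+`)
  })
  values <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      values[i, j] <- values[j, i] <-
        tethered_rmsd_xyz(xyz_s, posed[[i]], xyz_s, posed[[j]])
    }
  }
  structure(list(ids = poses$id, values = values), class = "td_pose_dist")
}

#' @export
print.td_pose_dist <- function(x, ...) {
  cat(sprintf("<td_pose_dist> %d poses, tethered RMSD %.2f-%.2f A\n",
              length(x$ids), min(x$values[upper.tri(x$values)]),
              max(x$values)))
  invisible(x)
}

cluster_spread <- function(values, members) {
  if (length(members) < 2) return(NA_real_)
  sub <- values[members, members, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' NMRCLUST-style clustering of a pose distance matrix
#'
#' Average-linkage agglomeration over all merge steps; at each step the
#' normalised average intra-cluster spread (mean pairwise distance within
#' multi-member clusters) and the normalised cluster count — both scaled
#' linearly onto \[1, n_steps\] — are summed, and the step with the minimal
#' combined penalty is chosen. Each cluster is represented by its medoid
#' (the member minimising mean distance to the rest).
#'
#' @param dist_matrix a `td_pose_dist` from [pairwise_pose_rmsd()].
#' @return a `td_clust`: labels tibble (pose_id, cluster, is_representative),
#'   penalty trace tibble, chosen step, and the hclust tree.
#' @export
nmrclust <- function(dist_matrix) {
  stopifnot(inherits(dist_matrix, "td_pose_dist"))
  v <- dist_matrix$values
  n <- nrow(v)
  if (n < 2) stop("need at least 2 poses to cluster")
  if (max(v) <= 1e-8) {
    # degenerate all-equal input: a single cluster, medoid = first pose
    return(structure(list(
      labels = tibble::tibble(pose_id = dist_matrix$ids,
                              cluster = rep(1L, n),
                              is_representative = seq_len(n) == 1),
      penalty_trace = tibble::tibble(step = integer(0),
                                     n_clusters = integer(0),
                                     spread = numeric(0),
                                     penalty = numeric(0)),
      chosen_step = n - 1L,
      tree = NULL,
      values = v), class = "td_clust"))
  }
  hc <- stats::hclust(stats::as.dist(v), method = "average")
  n_steps <- n - 1

  spread <- numeric(n_steps)
  n_clusters <- integer(n_steps)
  for (s in seq_len(n_steps)) {
    labels <- stats::cutree(hc, k = n - s)
    n_clusters[s] <- n - s
    sp <- vapply(split(seq_len(n), labels), cluster_spread,
                 numeric(1), values = v)
    spread[s] <- if (all(is.na(sp))) 0 else mean(sp, na.rm = TRUE)
  }
  norm01 <- function(x) {
    if (diff(range(x)) < 1e-12) rep(1, length(x))
    else 1 + (n_steps - 1) * (x - min(x)) / (max(x) - min(x))
  }
  penalty <- norm01(spread) + norm01(n_clusters)
  chosen <- which.min(penalty)

  labels <- stats::cutree(hc, k = n - chosen)
  reps <- vapply(split(seq_len(n), labels), function(members) {
    if (length(members) == 1) return(members)
    members[which.min(rowMeans(v[members, members, drop = FALSE]))]
  }, integer(1))

  structure(list(
    labels = tibble::tibble(
      pose_id = dist_matrix$ids,
      cluster = unname(labels),
      is_representative = seq_len(n) %in% reps),
    penalty_trace = tibble::tibble(
      step = seq_len(n_steps), n_clusters = n_clusters, spread = spread,
      penalty = penalty),
    chosen_step = chosen,
    tree = hc,
    values = v
  ), class = "td_clust")
}

#' @export
print.td_clust <- function(x, ...) {
  cat(sprintf("<td_clust> %d poses in %d clusters (chosen step %d)\n",
              nrow(x$labels), length(unique(x$labels$cluster)),
              x$chosen_step))
  invisible(x)
}

#' @export
tidy.td_clust <- function(x, ...) x$labels

#' @export
glance.td_clust <- function(x, ...) {
  tibble::tibble(
    n_poses = nrow(x$labels),
    n_clusters = length(unique(x$labels$cluster)),
    chosen_step = x$chosen_step,
    min_penalty = min(x$penalty_trace$penalty)
  )
}

#' Top clusters by membership
#'
#' Clusters ordered by decreasing size; ties broken by smaller mean
#' intra-cluster spread.
#'
#' @param result a `td_clust`.
#' @param k how many clusters to return (default 5, the published choice of
#'   representative poses carried forward).
#' @return tibble with cluster, size, spread, representative (pose id),
#'   first `k` rows of the ordering.
#' @export
top_clusters <- function(result, k = 5) {
  stopifnot(inherits(result, "td_clust"))
  idx <- split(seq_len(nrow(result$labels)), result$labels$cluster)
  summary <- tibble::tibble(
    cluster = as.integer(names(idx)),
    size = lengths(idx),
    spread = vapply(idx, function(m) {
      s <- cluster_spread(result$values, m)
      if (is.na(s)) 0 else s
    }, numeric(1)),
    representative = vapply(idx, function(m) {
      result$labels$pose_id[m[result$labels$is_representative[m]][1]]
    }, result$labels$pose_id[1])
  ) |>
    dplyr::arrange(dplyr::desc(.data$size), .data$spread)
  if (k > nrow(summary)) {
    warning(sprintf("only %d clusters available (k = %d); returning all",
                    nrow(summary), k), call. = FALSE)
    k <- nrow(summary)
  }
  summary[seq_len(k), , drop = FALSE]
}
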