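# Corrected mutual information between residue torsion distributions.
#
# The estimator is the plugin (histogram) MI of the discretised joint
# distribution, in nats, over fixed-width 15-degree bins. Significance is
# assessed per torsion pair against a permutation null (random frame
# permutation of one series destroys any coupling while preserving the
# marginals); the residue-level coupling is the summed excess MI
# (observed - null mean) over torsion pairs, zeroed wherever the observed
# MI does not exceed the null 95th percentile.

#' Discretise angles into fixed-width bins
#'
#' @param x angles in degrees (wrapped into \[-180, 180) internally).
#' @param n_bins number of equal-width bins over \[-180, 180).
#' @return integer bin indices in 1..n_bins.
#' @export
bin_angles <- function(x, n_bins = 24) {
  b <- floor((wrap_angle(x) + 180) / (360 / n_bins)) + 1L
  pmin.int(pmax.int(b, 1L), n_bins)
}

mi_from_bins <- function(ba, bb, n_bins) {
  joint <- tabulate(
    (ba - 1L) * n_bins + bb, nbins = n_bins * n_bins)
  n <- length(ba)
  p <- joint / n
  pa <- tabulate(ba, nbins = n_bins) / n
  pb <- tabulate(bb, nbins = n_bins) / n
  nz <- which(p > 0)
  ia <- ((nz - 1L) %/% n_bins) + 1L
  ib <- ((nz - 1L) %% n_bins) + 1L
  sum(p[nz] * log(p[nz] / (pa[ia] * pb[ib])))
}

#' Plugin mutual information between two torsion series
#'
#' @param a,b numeric angle vectors of equal length, degrees.
#' @param n_bins histogram bins over \[-180, 180) for each marginal.
#' @return MI in nats (>= 0 up to floating point).
#' @examples
#' x <- rep(c(-60, 180), 500)
#' pair_mutual_information(x, x)  # ln 2
#' @export
pair_mutual_information <- function(a, b, n_bins = 24) {
  if (length(a) != length(b))
    stop("torsion series have different lengths", call. = FALSE)
  mi_from_bins(bin_angles(a, n_bins), bin_angles(b, n_bins), n_bins)
}

# Deterministic per-pair RNG seed derived from the global seed and the
# pair's identity, so null distributions do not depend on the order in
# which pairs are visited (couplings are invariant under residue
# re-ordering).
pair_seed <- function(seed, label_i, label_j) {
  labs <- sort(c(label_i, label_j))
  h <- sum(utf8ToInt(paste(labs, collapse = "#")) *
             seq_len(nchar(paste(labs, collapse = "#"))))
  (as.integer(seed) %% 65011 + 1L) * 32003L + as.integer(h %% 32003)
}

# Observed MI plus permutation-null summary for one torsion pair. The null
# permutes the frames of `b`; returns mean and 95th percentile of the null
# MI distribution and the significance verdict (observed > null q95).
pair_null <- function(a, b, n_bins = 24, n_permutations = 100) {
  ba <- bin_angles(a, n_bins)
  bb <- bin_angles(b, n_bins)
  obs <- mi_from_bins(ba, bb, n_bins)
  null_mi <- vapply(seq_len(n_permutations), function(i) {
    mi_from_bins(ba, bb[sample.int(length(bb))], n_bins)
  }, numeric(1))
  list(mi = obs, null_mean = mean(null_mi),
       null_q95 = unname(stats::quantile(null_mi, 0.95)),
       significant = obs > unname(stats::quantile(null_mi, 0.95)))
}

#' Permutation-null summaries for every torsion pair
#'
#' For each cross-residue torsion pair, computes the observed MI and the
#' mean and 95th percentile of the MI under random frame permutations of
#' one series.
#'
#' @param torsion_set a torsion tibble from [extract_torsions()].
#' @param n_permutations permutations per pair (>= 50).
#' @param seed RNG seed (required; every stochastic step in this package
#'   takes an explicit seed).
#' @param n_bins histogram bins.
#' @return a tibble with one row per torsion pair: residue/torsion labels,
#'   `mi`, `null_mean`, `null_q95`, `significant`.
#' @export
coupling_null <- function(torsion_set, n_permutations = 100, seed,
                          n_bins = 24) {
  if (n_permutations < 50)
    stop("use at least 50 permutations for a stable 95th percentile")
  if (missing(seed)) stop("`seed` is required")
  pairs <- torsion_pairs(torsion_set)
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    li <- paste(torsion_set$residue[pairs$i[k]],
                torsion_set$torsion[pairs$i[k]])
    lj <- paste(torsion_set$residue[pairs$j[k]],
                torsion_set$torsion[pairs$j[k]])
    a <- torsion_set$angles[[pairs$i[k]]]
    b <- torsion_set$angles[[pairs$j[k]]]
    if (lj < li) { tmp <- a; a <- b; b <- tmp }  # canonical orientation
    set.seed(pair_seed(seed, li, lj))
    r <- pair_null(a, b, n_bins, n_permutations)
    out[[k]] <- tibble::tibble(
      residue_i = torsion_set$residue[pairs$i[k]],
      torsion_i = torsion_set$torsion[pairs$i[k]],
      residue_j = torsion_set$residue[pairs$j[k]],
      torsion_j = torsion_set$torsion[pairs$j[k]],
      mi = r$mi, null_mean = r$null_mean, null_q95 = r$null_q95,
      significant = r$significant)
  }
  dplyr::bind_rows(out)
}

# Cross-residue torsion pair index table. Omega is excluded by default
# (near-constant in real ensembles); constant series are skipped outright
# since their MI is identically zero.
torsion_pairs <- function(torsion_set, include_omega = FALSE) {
  keep <- if (include_omega) seq_len(nrow(torsion_set)) else
    which(torsion_set$torsion != "omega")
  keep <- keep[vapply(torsion_set$angles[keep],
                      function(x) length(unique(bin_angles(x))) > 1,
                      logical(1))]
  if (length(keep) < 2)
    return(tibble::tibble(i = integer(0), j = integer(0)))
  cmb <- utils::combn(keep, 2)
  same <- torsion_set$residue[cmb[1, ]] == torsion_set$residue[cmb[2, ]]
  tibble::tibble(i = cmb[1, !same], j = cmb[2, !same])
}

#' Residue-residue coupling matrix from torsion mutual information
#'
#' Builds the symmetric residue-pair coupling matrix: for each pair of
#' residues, the sum over their cross-residue torsion pairs of
#' `max(0, MI_observed - null_mean)`, with a torsion pair contributing only
#' when its observed MI exceeds the permutation-null 95th percentile. The
#' diagonal is zero; entries with no significant torsion pair are zero and
#' masked out.
#'
#' @inheritParams coupling_null
#' @param ensembles alternatively to `torsion_set`: a `td_ensemble` or list
#'   of ensembles sharing a topology; frames are concatenated (pooling
#'   independent simulation copies) before torsion extraction.
#' @param torsion_set a torsion tibble from [extract_torsions()].
#' @param include_omega include omega torsions (default off; near-constant).
#' @return a `td_coupling` object: residue labels, `values` matrix (nats),
#'   logical `mask` of significant pairs, and the run parameters.
#' @export
residue_coupling_matrix <- function(torsion_set = NULL, ensembles = NULL,
                                    n_bins = 24, n_permutations = 100, seed,
                                    include_omega = FALSE) {
  if (missing(seed)) stop("`seed` is required")
  if (is.null(torsion_set)) {
    if (is.null(ensembles)) stop("supply `torsion_set` or `ensembles`")
    torsion_set <- extract_torsions(pool_ensembles(ensembles))
  }
  residues <- unique(torsion_set$residue)
  if (length(residues) < 2) stop("need torsions from at least 2 residues")
  nres <- length(residues)
  values <- matrix(0, nres, nres, dimnames = list(residues, residues))
  mask <- matrix(FALSE, nres, nres, dimnames = list(residues, residues))
  pairs <- torsion_pairs(torsion_set, include_omega)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    li <- paste(torsion_set$residue[i], torsion_set$torsion[i])
    lj <- paste(torsion_set$residue[j], torsion_set$torsion[j])
    a <- torsion_set$angles[[i]]
    b <- torsion_set$angles[[j]]
    if (lj < li) { tmp <- a; a <- b; b <- tmp }  # canonical orientation
    set.seed(pair_seed(seed, li, lj))
    r <- pair_null(a, b, n_bins, n_permutations)
    if (r$significant) {
      ri <- match(torsion_set$residue[i], residues)
      rj <- match(torsion_set$residue[j], residues)
      excess <- max(0, r$mi - r$null_mean)
      values[ri, rj] <- values[ri, rj] + excess
      values[rj, ri] <- values[ri, rj]
      mask[ri, rj] <- mask[rj, ri] <- TRUE
    }
  }
  structure(list(residues = residues, values = values, mask = mask,
                 n_bins = n_bins, n_permutations = n_permutations,
                 seed = seed),
            class = "td_coupling")
}

#' Pool frames of several topology-matched ensembles
#'
#' @param ensembles a `td_ensemble` or a list of them (e.g. independent
#'   simulation copies run from different seeds).
#' @return a single `td_ensemble` with concatenated frames.
#' @export
pool_ensembles <- function(ensembles) {
  if (inherits(ensembles, "td_ensemble")) return(ensembles)
  stopifnot(is.list(ensembles), length(ensembles) >= 1)
  ref <- ensembles[[1]]
  for (k in seq_along(ensembles)) {
    e <- ensembles[[k]]
    if (!inherits(e, "td_ensemble"))
      stop("all elements must be td_ensemble objects")
    if (e$topology_hash != ref$topology_hash)
      stop(sprintf("ensemble %d does not share the reference topology", k))
  }
  new_ensemble(ref$atoms, do.call(rbind, lapply(ensembles, `[[`, "xyz")))
}

#' @export
print.td_coupling <- function(x, ...) {
  cat(sprintf(
    "<td_coupling> %d residues, %d significant pairs, max coupling %.3f nats\n",
    length(x$residues), sum(x$mask[upper.tri(x$mask)]),
    max(x$values)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a coupling matrix into an edge table
#'
#' @param x a `td_coupling`.
#' @param ... unused.
#' @return tibble with residue_i, residue_j, coupling (nats), significant;
#'   upper triangle only.
#' @export
tidy.td_coupling <- function(x, ...) {
  ut <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    residue_i = x$residues[ut[, 1]],
    residue_j = x$residues[ut[, 2]],
    coupling = x$values[ut],
    significant = x$mask[ut]
  )
}

#' @export
glance.td_coupling <- function(x, ...) {
  tibble::tibble(
    n_residues = length(x$residues),
    n_significant_pairs = sum(x$mask[upper.tri(x$mask)]),
    max_coupling = max(x$values),
    n_bins = x$n_bins, n_permutations = x$n_permutations, seed = x$seed
  )
}

#' Group strongly coupled residues into candidate interface sites
#'
#' Average-linkage hierarchical clustering of the coupling matrix on the
#' distance `max(values) - value`; the tree is cut at the height
#' corresponding to `min_coupling` and groups whose mean internal coupling
#' reaches `min_coupling` are returned, largest first.
#'
#' @param matrix a `td_coupling`.
#' @param min_coupling minimum mean internal coupling (nats) for a reported
#'   site group.
#' @return a tibble of site groups: label, residues (list-column),
#'   n_residues, mean_internal_coupling; zero rows if nothing couples.
#' @export
cluster_sites <- function(matrix, min_coupling = 0.1) {
  stopifnot(inherits(matrix, "td_coupling"))
  empty <- tibble::tibble(label = character(0), residues = list(),
                          n_residues = integer(0),
                          mean_internal_coupling = numeric(0))
  v <- matrix$values
  if (max(v) <= 0) return(empty)
  d <- stats::as.dist(max(v) - v)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, h = max(v) - min_coupling)
  groups <- split(matrix$residues, labels)
  rows <- list()
  for (g in groups) {
    if (length(g) < 2) next
    idx <- match(g, matrix$residues)
    sub <- v[idx, idx]
    mic <- mean(sub[upper.tri(sub)])
    if (mic >= min_coupling)
      rows[[length(rows) + 1]] <- tibble::tibble(
        residues = list(g), n_residues = length(g),
        mean_internal_coupling = mic)
  }
  if (length(rows) == 0) return(empty)
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$n_residues),
                   dplyr::desc(.data$mean_internal_coupling))
  out$label <- paste0("site", seq_len(nrow(out)))
  out[, c("label", "residues", "n_residues", "mean_internal_coupling")]
}

#' Export significant couplings as a network edge list
#'
#' Writes a TSV of residue-pair edges (weight = coupling in nats) suitable
#' for force-directed network layout tools.
#'
#' @param matrix a `td_coupling`.
#' @param path output TSV path.
#' @param min_weight drop edges below this coupling.
#' @return the edge tibble, invisibly.
#' @export
export_network <- function(matrix, path, min_weight = 0) {
  stopifnot(inherits(matrix, "td_coupling"))
  edges <- tidy(matrix) |>
    dplyr::filter(.data$significant, .data$coupling >= min_weight) |>
    dplyr::select("residue_i", "residue_j", weight = "coupling")
  readr::write_tsv(edges, path)
  invisible(edges)
}
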