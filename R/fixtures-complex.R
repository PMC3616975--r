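# Planted-feature two-domain complexes (ground-truth test beds for the
# interface metrics) and planted pose groups (test bed for clustering).

feature_distance <- function(complex, feat, classes) {
  a <- select_atoms(complex, chain = "A", resno = feat$res_a)
  b <- select_atoms(complex, chain = "B", resno = feat$res_b)
  cls <- function(s) classes[classes$resname == s$resname[1], ]
  if (feat$kind == "hydrophobic_pair") {
    min_interdomain_distance(coords(sidechain_atoms(a)),
                             coords(sidechain_atoms(b)))
  } else if (feat$kind == "ionic_pair") {
    min_interdomain_distance(
      coords(a[a$name %in% cls(a)$charged_atoms[[1]], ]),
      coords(b[b$name %in% cls(b)$charged_atoms[[1]], ]))
  } else if (feat$kind == "stacking_pair") {
    ca <- colMeans(coords(a[a$name %in% cls(a)$ring_atoms[[1]], ]))
    cb <- colMeans(coords(b[b$name %in% cls(b)$ring_atoms[[1]], ]))
    vnorm(ca - cb)
  } else stop(sprintf("unknown feature kind '%s'", feat$kind))
}

#' Two-domain complex with planted interface features
#'
#' Builds two helical domains (chains A and B) and rigidly places chain B so
#' that each planted feature's defining distance — minimum side-chain
#' heavy-atom distance for `hydrophobic_pair`, minimum charged-group atom
#' distance for `ionic_pair`, ring-centroid distance for `stacking_pair` —
#' hits its target within 0.05 A. Placement is solved by Nelder-Mead over
#' the rigid transform of chain B; an unsatisfiable feature set errors.
#'
#' @param sequence_a,sequence_b one-letter sequences of the two domains.
#' @param features list of `list(kind =, res_a =, res_b =, distance =)`
#'   entries; `res_a`/`res_b` are residue numbers on chains A/B.
#' @param gap when `features` is empty: translation distance (A) between
#'   the two domain centroids along x.
#' @return list with `complex` (atom tibble, chains A and B),
#'   `domain_a`/`domain_b` definitions and the feature `ledger` tibble
#'   (planted kind, residues, target and achieved distance).
#' @export
make_two_domain_complex <- function(sequence_a, sequence_b,
                                    features = list(), gap = 10) {
  dom_a <- make_helix_domain(sequence_a, chain = "A")
  dom_b <- make_helix_domain(sequence_b, chain = "B")
  classes <- residue_classes()

  na <- max(dom_a$resno); nb <- max(dom_b$resno)
  def_a <- domain_def("A", "A", 1, na)
  def_b <- domain_def("B", "B", 1, nb)

  if (length(features) == 0) {
    shift <- heavy_centroid(dom_a) - heavy_centroid(dom_b)
    dom_b <- transform_structure(dom_b, t = shift + c(gap, 0, 0))
    cx <- dplyr::bind_rows(dom_a, dom_b)
    cx$serial <- seq_len(nrow(cx))
    return(list(complex = cx, domain_a = def_a, domain_b = def_b,
                ledger = tibble::tibble(kind = character(0))))
  }

  # start: B beside A, roughly feature-to-feature along x
  fa <- heavy_centroid(select_atoms(dom_a, resno = features[[1]]$res_a))
  fb <- heavy_centroid(select_atoms(dom_b, resno = features[[1]]$res_b))
  dom_b0 <- transform_structure(dom_b, t = fa - fb + c(8, 0, 0))

  xyz_b0 <- coords(dom_b0)
  cen_b <- colMeans(xyz_b0)
  build <- function(par) {
    R <- rotation_about_axis(c(0, 0, 1), par[4]) %*%
      rotation_about_axis(c(0, 1, 0), par[5]) %*%
      rotation_about_axis(c(1, 0, 0), par[6])
    b <- set_coords(dom_b0, sweep(sweep(xyz_b0, 2, cen_b) %*% t(R), 2,
                                  cen_b + par[1:3], `+`))
    cx <- dplyr::bind_rows(dom_a, b)
    cx$serial <- seq_len(nrow(cx))
    cx
  }
  xyz_a <- coords(dom_a)
  objective <- function(par) {
    cx <- build(par)
    err <- sum(vapply(features, function(f)
      (feature_distance(cx, f, classes) - f$distance)^2, numeric(1)))
    # soft steric term keeps the optimizer from fusing the two domains
    xb <- coords(cx[cx$chain == "B", , drop = FALSE])
    d2 <- outer(rowSums(xyz_a^2), rowSums(xb^2), `+`) - 2 * xyz_a %*% t(xb)
    close <- d2[d2 < 2.8^2]
    err + 10 * sum((2.8 - sqrt(pmax(close, 0)))^2)
  }
  fit <- stats::optim(rep(0, 6), objective, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  if (sqrt(fit$value / length(features)) > 0.04) {
    fit2 <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                         control = list(maxit = 4000, reltol = 1e-14))
    if (fit2$value < fit$value) fit <- fit2
  }
  cx <- build(fit$par)
  achieved <- vapply(features, function(f)
    feature_distance(cx, f, classes), numeric(1))
  targets <- vapply(features, `[[`, numeric(1), "distance")
  if (any(abs(achieved - targets) > 0.05))
    stop("infeasible feature set: placement cannot satisfy all target distances",
         call. = FALSE)
  list(
    complex = cx, domain_a = def_a, domain_b = def_b,
    ledger = tibble::tibble(
      kind = vapply(features, `[[`, character(1), "kind"),
      res_a = vapply(features, `[[`, numeric(1), "res_a"),
      res_b = vapply(features, `[[`, numeric(1), "res_b"),
      target = targets, achieved = achieved)
  )
}

#' Planted pose groups for clustering tests
#'
#' Generates `n_groups` clusters of poses: group centers are translations of
#' the mobile domain spaced `separation` apart in the tethered-RMSD metric
#' (pure rigid translations, for which tethered RMSD equals the translation
#' distance exactly), and members jitter around their center with an RMS
#' displacement of `spread`.
#'
#' @param n_groups,n_per_group cluster count and size.
#' @param separation center-to-center tethered RMSD between neighbouring
#'   groups, A (must exceed `spread`).
#' @param spread RMS within-group displacement, A.
#' @param seed RNG seed.
#' @return pose manifest tibble with a `true_group` column.
#' @export
make_pose_groups <- function(n_groups, n_per_group, separation = 20,
                             spread = 1, seed = 1) {
  stopifnot(separation > spread)
  set.seed(seed)
  rows <- list()
  id <- 0L
  for (g in seq_len(n_groups)) {
    center <- c(0, (g - 1) * separation, 0)
    for (m in seq_len(n_per_group)) {
      id <- id + 1L
      t <- center + stats::rnorm(3, sd = spread / sqrt(3))
      r <- pose_row(id, diag(3), t, seed = seed)
      r$true_group <- g
      rows[[id]] <- r
    }
  }
  dplyr::bind_rows(rows)
}
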