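# Cross-domain contact detectors: hydrophobic packing, ionic contacts and
# salt bridges, aromatic ring stacking. All distances are heavy-atom
# distances in angstroms; each residue pair is counted once.

split_domains <- function(complex, domain_a, domain_b) {
  mask_a <- selection_mask(complex, domain_a, NULL, NULL, NULL)
  mask_b <- selection_mask(complex, domain_b, NULL, NULL, NULL)
  if (any(mask_a & mask_b)) stop("domain definitions overlap", call. = FALSE)
  list(a = complex[mask_a, , drop = FALSE],
       b = complex[mask_b, , drop = FALSE])
}

# Minimum distance between two residues over the given atom subsets.
residue_min_dist <- function(res_a, res_b) {
  if (nrow(res_a) == 0 || nrow(res_b) == 0) return(Inf)
  min_interdomain_distance(coords(res_a), coords(res_b))
}

per_residue_split <- function(dom, atom_filter) {
  keep <- atom_filter(dom)
  split(keep, residue_key(keep$chain, keep$resno, keep$insert))
}

#' Hydrophobic contacts across a two-domain interface
#'
#' Unique cross-domain pairs of hydrophobic residues whose side-chain heavy
#' atoms approach within `cutoff` (inclusive).
#'
#' @param complex atom tibble with both domains.
#' @param domain_a,domain_b [domain_def()] rows.
#' @param cutoff contact distance, A (published panel uses 5 A).
#' @param classes a [residue_classes()] table (override to change the
#'   classification).
#' @return tibble: residue_a, residue_b, resname_a, resname_b, distance.
#' @export
hydrophobic_contacts <- function(complex, domain_a, domain_b, cutoff = 5,
                                 classes = residue_classes()) {
  doms <- split_domains(complex, domain_a, domain_b)
  hydro <- classes$resname[classes$hydrophobic]
  filt <- function(dom) sidechain_atoms(dom[dom$resname %in% hydro, ,
                                            drop = FALSE])
  contact_pairs(doms$a, doms$b, filt, filt, cutoff)
}

contact_pairs <- function(dom_a, dom_b, filt_a, filt_b, cutoff) {
  ra <- per_residue_split(dom_a, filt_a)
  rb <- per_residue_split(dom_b, filt_b)
  out <- list()
  for (ka in names(ra)) {
    for (kb in names(rb)) {
      d <- residue_min_dist(ra[[ka]], rb[[kb]])
      if (d <= cutoff)
        out[[length(out) + 1]] <- tibble::tibble(
          residue_a = ka, residue_b = kb,
          resname_a = ra[[ka]]$resname[1], resname_b = rb[[kb]]$resname[1],
          distance = d)
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(residue_a = character(0), residue_b = character(0),
                          resname_a = character(0), resname_b = character(0),
                          distance = numeric(0)))
  dplyr::bind_rows(out)
}

#' Ionic contacts across a two-domain interface
#'
#' Unique cross-domain pairs of oppositely charged residues whose
#' charged-group atoms (carboxylate oxygens, lysine NZ, arginine guanidinium
#' nitrogens, histidine ring nitrogens) approach within `cutoff`
#' (inclusive; published panel uses 6 A).
#'
#' @inheritParams hydrophobic_contacts
#' @return tibble: residue_a, residue_b, resname_a, resname_b, sign_a,
#'   sign_b, distance.
#' @export
ionic_contacts <- function(complex, domain_a, domain_b, cutoff = 6,
                           classes = residue_classes()) {
  doms <- split_domains(complex, domain_a, domain_b)
  charged <- classes$resname[classes$positive | classes$negative]
  charged_filter <- function(dom) {
    keep <- dom[dom$resname %in% charged, , drop = FALSE]
    ok <- mapply(function(rn, nm) {
      nm %in% classes$charged_atoms[[match(rn, classes$resname)]]
    }, keep$resname, keep$name)
    keep[as.logical(ok), , drop = FALSE]
  }
  pairs <- contact_pairs(doms$a, doms$b, charged_filter, charged_filter,
                         cutoff)
  if (nrow(pairs) == 0)
    return(tibble::tibble(residue_a = character(0), residue_b = character(0),
                          resname_a = character(0), resname_b = character(0),
                          sign_a = integer(0), sign_b = integer(0),
                          distance = numeric(0)))
  sign_of <- function(rn) ifelse(classes$positive[match(rn, classes$resname)],
                                 1L, -1L)
  pairs$sign_a <- sign_of(pairs$resname_a)
  pairs$sign_b <- sign_of(pairs$resname_b)
  pairs[pairs$sign_a * pairs$sign_b < 0, , drop = FALSE]
}

#' Salt bridges
#'
#' The subset of [ionic_contacts()] whose minimum charged-group atom
#' distance is within the (stricter) salt-bridge cutoff.
#'
#' @inheritParams ionic_contacts
#' @param cutoff salt-bridge distance, A (default 4).
#' @export
salt_bridges <- function(complex, domain_a, domain_b, cutoff = 4,
                         classes = residue_classes()) {
  ionic_contacts(complex, domain_a, domain_b, cutoff, classes)
}

#' Aromatic stacking pairs
#'
#' Cross-domain aromatic residue pairs whose ring centroids (arithmetic mean
#' of the ring heavy atoms) lie within \[d_min, d_max\] — the range generally
#' accepted for pi-pi stacking.
#'
#' @inheritParams hydrophobic_contacts
#' @param d_min,d_max centroid distance window, A (defaults 4.5 and 7.0).
#' @param include_intra also report pairs within one domain.
#' @return tibble: residue_a, residue_b, resname_a, resname_b,
#'   centroid_distance.
#' @export
stacking_pairs <- function(complex, domain_a, domain_b, d_min = 4.5,
                           d_max = 7.0, classes = residue_classes(),
                           include_intra = FALSE) {
  doms <- split_domains(complex, domain_a, domain_b)
  ring_centroids <- function(dom) {
    arom <- dom[dom$resname %in% classes$resname[classes$aromatic], ,
                drop = FALSE]
    if (nrow(arom) == 0) return(NULL)
    by_res <- split(arom, residue_key(arom$chain, arom$resno, arom$insert))
    rows <- lapply(names(by_res), function(k) {
      res <- by_res[[k]]
      ring <- res[res$name %in%
                    classes$ring_atoms[[match(res$resname[1],
                                              classes$resname)]], ,
                  drop = FALSE]
      if (nrow(ring) == 0) return(NULL)
      cen <- colMeans(coords(ring))
      tibble::tibble(residue = k, resname = res$resname[1],
                     cx = cen[1], cy = cen[2], cz = cen[3])
    })
    dplyr::bind_rows(rows)
  }
  ca <- ring_centroids(doms$a)
  cb <- ring_centroids(doms$b)
  empty <- tibble::tibble(residue_a = character(0), residue_b = character(0),
                          resname_a = character(0), resname_b = character(0),
                          centroid_distance = numeric(0))
  pair_up <- function(p, q) {
    if (is.null(p) || is.null(q) || nrow(p) == 0 || nrow(q) == 0)
      return(empty)
    out <- list()
    for (i in seq_len(nrow(p))) {
      for (j in seq_len(nrow(q))) {
        if (p$residue[i] == q$residue[j]) next
        d <- vnorm(c(p$cx[i] - q$cx[j], p$cy[i] - q$cy[j], p$cz[i] - q$cz[j]))
        if (d >= d_min && d <= d_max)
          out[[length(out) + 1]] <- tibble::tibble(
            residue_a = p$residue[i], residue_b = q$residue[j],
            resname_a = p$resname[i], resname_b = q$resname[j],
            centroid_distance = d)
      }
    }
    if (length(out) == 0) empty else dplyr::bind_rows(out)
  }
  res <- pair_up(ca, cb)
  if (include_intra) {
    intra <- function(p) {
      if (is.null(p) || nrow(p) < 2) return(empty)
      out <- pair_up(p, p)
      out[out$residue_a < out$residue_b, , drop = FALSE]
    }
    res <- dplyr::bind_rows(res, intra(ca), intra(cb))
  }
  res
}

#' Full interface report for one complex conformation
#'
#' Bundles the metric panel evaluated on a single conformation: buried
#' surface area, hydrophobic and ionic contact lists, salt bridges and
#' stacking pairs.
#'
#' @inheritParams hydrophobic_contacts
#' @param hydrophobic_cutoff,ionic_cutoff,salt_bridge_cutoff,stacking_range
#'   metric cutoffs, A.
#' @param probe,n_points SASA quadrature settings.
#' @return a `td_interface` object; `tidy()` gives the one-row summary.
#' @export
interface_report <- function(complex, domain_a, domain_b,
                             hydrophobic_cutoff = 5, ionic_cutoff = 6,
                             salt_bridge_cutoff = 4,
                             stacking_range = c(4.5, 7.0),
                             probe = 1.4, n_points = 960,
                             classes = residue_classes()) {
  structure(list(
    bsa = buried_surface_area(complex, domain_a, domain_b, probe, n_points),
    hydrophobic = hydrophobic_contacts(complex, domain_a, domain_b,
                                       hydrophobic_cutoff, classes),
    ionic = ionic_contacts(complex, domain_a, domain_b, ionic_cutoff,
                           classes),
    salt_bridges = salt_bridges(complex, domain_a, domain_b,
                                salt_bridge_cutoff, classes),
    stacking = stacking_pairs(complex, domain_a, domain_b,
                              stacking_range[1], stacking_range[2], classes)
  ), class = "td_interface")
}

#' @export
print.td_interface <- function(x, ...) {
  cat(sprintf(
    "<td_interface> BSA %.0f A^2 | %d hydrophobic, %d ionic (%d salt bridges), %d stacking\n",
    x$bsa, nrow(x$hydrophobic), nrow(x$ionic), nrow(x$salt_bridges),
    nrow(x$stacking)))
  invisible(x)
}

#' @export
tidy.td_interface <- function(x, ...) {
  tibble::tibble(
    bsa = x$bsa,
    n_hydrophobic = nrow(x$hydrophobic),
    n_ionic = nrow(x$ionic),
    n_salt_bridges = nrow(x$salt_bridges),
    n_stacking = nrow(x$stacking)
  )
}
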