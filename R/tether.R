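# Linker-reach filter: poses whose inter-domain termini are too far apart
# to be bridged by the covalent linker are discarded.

#' Tether specification
#'
#' @param static_terminus residue number of the linker attachment on the
#'   static domain (its C-terminal residue).
#' @param mobile_terminus residue number of the linker attachment on the
#'   mobile domain (its N-terminal residue).
#' @param cutoff maximum Calpha-Calpha termini distance the linker can
#'   bridge, A. The default 60 A is the published filter value.
#' @param n_linker_residues optional linker length in residues; enables the
#'   physical extension bound [linker_max_extension()] as a sanity check.
#' @return a `td_tether_spec` list.
#' @export
tether_spec <- function(static_terminus, mobile_terminus, cutoff = 60,
                        n_linker_residues = NULL) {
  stopifnot(cutoff > 0)
  structure(list(static_terminus = static_terminus,
                 mobile_terminus = mobile_terminus, cutoff = cutoff,
                 n_linker_residues = n_linker_residues),
            class = "td_tether_spec")
}

#' Maximum Calpha-Calpha extension of an n-residue linker
#'
#' Fully extended polypeptide bound of 3.8 A per residue.
#'
#' @param n_linker_residues number of linker residues (>= 1).
#' @return maximum reach in angstroms.
#' @export
linker_max_extension <- function(n_linker_residues) {
  stopifnot(n_linker_residues >= 1)
  n_linker_residues * 3.8
}

terminus_ca <- function(structure, resno) {
  row <- structure[structure$resno == resno & structure$name == "CA", ,
                   drop = FALSE]
  if (nrow(row) == 0)
    stop(sprintf("no CA atom found for terminus residue %d", resno),
         call. = FALSE)
  unlist(row[1, c("x", "y", "z")])
}

#' Termini distance of each pose
#'
#' Euclidean distance between the Calpha of the static domain's linker
#' terminus and the Calpha of the mobile domain's linker terminus in the
#' posed coordinates.
#'
#' @param poses pose manifest tibble.
#' @param static,mobile the two domains (reference frames).
#' @param spec a [tether_spec()].
#' @return `poses` with an added `termini_distance` column (A).
#' @export
termini_distance <- function(poses, static, mobile, spec) {
  stopifnot(inherits(spec, "td_tether_spec"))
  ca_s <- terminus_ca(static, spec$static_terminus)
  ca_m0 <- terminus_ca(mobile, spec$mobile_terminus)
  d <- numeric(nrow(poses))
  for (k in seq_len(nrow(poses))) {
    tr <- pose_transform(poses[k, ])
    d[k] <- vnorm(as.vector(tr$R %*% ca_m0) + tr$t - ca_s)
  }
  poses$termini_distance <- d
  poses
}

#' Filter poses by linker reach
#'
#' Keeps poses whose termini distance is at most the cutoff (inclusive),
#' preserving order. The filter is idempotent and monotone in the cutoff.
#'
#' @inheritParams termini_distance
#' @return the surviving poses (with `termini_distance` column); a one-row
#'   report tibble (n_in, n_kept, n_dropped, cutoff) is attached as
#'   attribute `"tether_report"` (see [tether_report()]).
#' @export
filter_by_tether <- function(poses, static, mobile, spec) {
  if (nrow(poses) == 0) stop("no poses to filter")
  if (!"termini_distance" %in% names(poses))
    poses <- termini_distance(poses, static, mobile, spec)
  kept <- poses[poses$termini_distance <= spec$cutoff, , drop = FALSE]
  attr(kept, "tether_report") <- tibble::tibble(
    n_in = nrow(poses), n_kept = nrow(kept),
    n_dropped = nrow(poses) - nrow(kept), cutoff = spec$cutoff)
  kept
}

#' @rdname filter_by_tether
#' @param x a filtered pose tibble returned by `filter_by_tether()`.
#' @export
tether_report <- function(x) attr(x, "tether_report")
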