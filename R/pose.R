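# Rigid-body pose representation and the Gaussian perturbation sampler.
#
# A pose is one row of a "pose manifest" tibble: an id, provenance
# (parent_id, seed) and a rigid transform (r11..r33, tx, ty, tz) applied to
# the mobile domain's reference coordinates as x_posed = R x + t (column
# vectors). The static domain never moves.

pose_row <- function(id, R, t, parent_id = NA_integer_, seed = NA_integer_) {
  tibble::tibble(
    id = as.integer(id), parent_id = as.integer(parent_id),
    seed = as.integer(seed),
    r11 = R[1, 1], r12 = R[1, 2], r13 = R[1, 3],
    r21 = R[2, 1], r22 = R[2, 2], r23 = R[2, 3],
    r31 = R[3, 1], r32 = R[3, 2], r33 = R[3, 3],
    tx = t[1], ty = t[2], tz = t[3]
  )
}

#' Extract the rigid transform of a pose row
#' @param pose a one-row pose tibble.
#' @return list with 3x3 `R` and 3-vector `t`.
#' @export
pose_transform <- function(pose) {
  stopifnot(nrow(pose) == 1)
  list(R = matrix(c(pose$r11, pose$r21, pose$r31,
                    pose$r12, pose$r22, pose$r32,
                    pose$r13, pose$r23, pose$r33), 3, 3),
       t = c(pose$tx, pose$ty, pose$tz))
}

#' Identity pose
#' @param id pose id.
#' @return a one-row pose tibble with the identity transform.
#' @export
identity_pose <- function(id = 0L) pose_row(id, diag(3), c(0, 0, 0))

#' Apply a pose to the mobile domain
#'
#' @param mobile the mobile domain's reference atom tibble.
#' @param pose a one-row pose tibble.
#' @return the posed mobile structure.
#' @export
apply_pose <- function(mobile, pose) {
  tr <- pose_transform(pose)
  set_coords(mobile, sweep(coords(mobile) %*% t(tr$R), 2, tr$t, `+`))
}

heavy_centroid <- function(structure) colMeans(coords(structure))

posed_centroid <- function(mobile, pose) {
  tr <- pose_transform(pose)
  as.vector(tr$R %*% heavy_centroid(mobile) + tr$t)
}

min_interdomain_distance <- function(xyz_a, xyz_b) {
  # smallest pairwise distance between two coordinate sets
  min(sqrt(outer(rowSums(xyz_a^2), rowSums(xyz_b^2), `+`) -
             2 * xyz_a %*% t(xyz_b)))
}

#' Seed a two-domain pose from nominated site patches
#'
#' Places the mobile domain so that the two site patches face each other:
#' the mobile domain is rotated so its patch-outward axis (patch centroid
#' minus domain centroid) anti-aligns with the static one, then slid along
#' the line through the patch centroids until the minimum interdomain
#' heavy-atom distance equals `contact_gap` (bisection, converged to well
#' under 0.1 A).
#'
#' @param static,mobile atom tibbles for the two domains (reference frames).
#' @param site_static,site_mobile residue numbers of the nominated site
#'   patch on each domain.
#' @param contact_gap target minimum interdomain heavy-atom distance, A.
#' @return a one-row pose tibble (id 0).
#' @export
seed_placement <- function(static, mobile, site_static, site_mobile,
                           contact_gap = 4) {
  assert_structure(static); assert_structure(mobile)
  patch_s <- heavy_centroid(select_atoms(static, resno = site_static))
  patch_m <- heavy_centroid(select_atoms(mobile, resno = site_mobile))
  cen_s <- heavy_centroid(static)
  cen_m <- heavy_centroid(mobile)

  burial_check <- function(patch, cen, xyz, label) {
    # exposure proxy: few atoms should lie beyond the patch centroid along
    # its outward direction; a buried patch has protein on all sides
    u <- vunit(patch - cen)
    beyond <- mean((sweep(xyz, 2, patch) %*% u) > 3)
    if (beyond > 0.25)
      warning(sprintf("%s site patch looks buried (%.0f%% of atoms beyond it)",
                      label, 100 * beyond), call. = FALSE)
  }
  burial_check(patch_s, cen_s, coords(static), "static")
  burial_check(patch_m, cen_m, coords(mobile), "mobile")

  u_s <- vunit(patch_s - cen_s)
  u_m <- vunit(patch_m - cen_m)
  # rotate mobile (about its centroid) so u_m -> -u_s
  target <- -u_s
  ax <- vcross(u_m, target)
  if (vnorm(ax) < 1e-10) {
    R0 <- if (sum(u_m * target) > 0) diag(3) else
      rotation_about_axis(orthonormal_complement(u_m)[, 1], 180)
  } else {
    R0 <- rotation_about_axis(ax, rad2deg(atan2(vnorm(ax), sum(u_m * target))))
  }

  xyz_m0 <- coords(mobile)
  place <- function(d) {
    # mobile patch centroid sits at patch_s + d * u_s, outward axes opposed
    new_cen <- patch_s + d * u_s + vnorm(patch_m - cen_m) * u_s
    t <- new_cen - as.vector(R0 %*% cen_m)
    list(R = R0, t = t)
  }
  mind <- function(d) {
    tr <- place(d)
    min_interdomain_distance(coords(static),
                             sweep(xyz_m0 %*% t(tr$R), 2, tr$t, `+`))
  }
  lo <- -vnorm(patch_m - cen_m) - vnorm(patch_s - cen_s)
  hi <- 50
  if (mind(hi) < contact_gap) hi <- 200
  if (mind(hi) < contact_gap || mind(lo) > contact_gap)
    stop("cannot achieve the requested contact gap for these site patches",
         call. = FALSE)
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (mind(mid) < contact_gap) lo <- mid else hi <- mid
    if (hi - lo < 1e-3) break
  }
  tr <- place((lo + hi) / 2)
  pose_row(0L, tr$R, tr$t)
}

orthonormal_complement <- function(u) {
  u <- vunit(u)
  e <- diag(3)[, which.min(abs(u))]
  p1 <- vunit(e - sum(e * u) * u)
  p2 <- vcross(u, p1)
  cbind(p1, p2)
}

#' Gaussian perturbation parameters
#'
#' Defaults follow the published rigid-body sampling scheme: a Gaussian
#' rotation of 8 degrees SD about the axis through the two domain centers, a
#' tilt of 8 degrees SD away from that axis, and Gaussian translations of
#' 3 A SD along the center line and 8 A SD in each perpendicular direction.
#'
#' @param axial_rotation_sd SD of the rotation about the center axis, deg.
#' @param tilt_sd SD of the tilt of that axis, deg.
#' @param axial_translation_sd SD of the translation along the center line, A.
#' @param perpendicular_translation_sd SD of each perpendicular translation, A.
#' @return a `td_perturbation_spec` list.
#' @export
perturbation_spec <- function(axial_rotation_sd = 8, tilt_sd = 8,
                              axial_translation_sd = 3,
                              perpendicular_translation_sd = 8) {
  stopifnot(axial_rotation_sd >= 0, tilt_sd >= 0, axial_translation_sd >= 0,
            perpendicular_translation_sd >= 0)
  structure(list(axial_rotation_sd = axial_rotation_sd, tilt_sd = tilt_sd,
                 axial_translation_sd = axial_translation_sd,
                 perpendicular_translation_sd = perpendicular_translation_sd),
            class = "td_perturbation_spec")
}

# One perturbation of `pose`, drawing from the current RNG stream.
# Draw order (fixed for determinism): axial translation, two perpendicular
# translations, axial rotation angle, tilt angle, tilt-axis direction.
# Operations compose in the stated order: translate, rotate about the
# center axis, tilt about a uniformly random perpendicular axis; rotations
# act about the (translated) mobile centroid so translation components stay
# exactly Gaussian.
perturb_pose <- function(pose, spec, static, mobile, id = NA_integer_,
                         seed = NA_integer_) {
  cen_s <- heavy_centroid(static)
  cen_m <- posed_centroid(mobile, pose)
  u <- vunit(cen_m - cen_s)
  P <- orthonormal_complement(u)

  d_ax <- stats::rnorm(1, 0, spec$axial_translation_sd)
  d_p1 <- stats::rnorm(1, 0, spec$perpendicular_translation_sd)
  d_p2 <- stats::rnorm(1, 0, spec$perpendicular_translation_sd)
  alpha <- stats::rnorm(1, 0, spec$axial_rotation_sd)
  beta <- stats::rnorm(1, 0, spec$tilt_sd)
  tau <- stats::runif(1, 0, 360)

  dt <- d_ax * u + d_p1 * P[, 1] + d_p2 * P[, 2]
  m <- cos(deg2rad(tau)) * P[, 1] + sin(deg2rad(tau)) * P[, 2]
  Rax <- rotation_about_axis(u, alpha)
  Rtl <- rotation_about_axis(m, beta)
  Rd <- Rtl %*% Rax

  tr <- pose_transform(pose)
  new_cen <- cen_m + dt
  # y' = Rd (y + dt - new_cen) + new_cen applied to posed coords y = R x + t
  R_new <- Rd %*% tr$R
  t_new <- as.vector(Rd %*% (tr$t + dt - new_cen)) + new_cen
  pose_row(id, R_new, t_new, parent_id = pose$id, seed = seed)
}

#' Sample rigid-body perturbations of a seed pose
#'
#' Draws `n` independent Gaussian perturbations of the seed pose (each pose
#' perturbs the seed, not the previous pose). Deterministic for a fixed
#' seed.
#'
#' @param seed_pose one-row pose tibble (e.g. from [seed_placement()]).
#' @param spec a [perturbation_spec()].
#' @param n number of poses.
#' @param seed RNG seed.
#' @param static,mobile the two domains (reference frames) — needed for the
#'   center axis.
#' @return a pose manifest tibble with `n` rows, ids 1..n.
#' @examples
#' dom <- make_helix_domain(strrep("A", 8))
#' mob <- transform_structure(dom, t = c(30, 0, 0))
#' poses <- sample_poses(identity_pose(), perturbation_spec(), 10,
#'                       seed = 1, static = dom, mobile = mob)
#' @export
sample_poses <- function(seed_pose, spec, n, seed, static, mobile) {
  stopifnot(n >= 1)
  set.seed(seed)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    out[[k]] <- perturb_pose(seed_pose, spec, static, mobile, id = k,
                             seed = seed)
  }
  dplyr::bind_rows(out)
}

#' Count interdomain clashes for each pose
#'
#' Counts interdomain heavy-atom pairs closer than `min_dist` and flags
#' poses whose count exceeds `max_violations`. Poses are annotated, not
#' dropped (use `strict = TRUE` downstream to drop flagged poses); local
#' repacking is out of scope so mild overlap is tolerated.
#'
#' @param poses pose manifest tibble.
#' @param static,mobile the two domains (reference frames).
#' @param min_dist clash distance threshold, A.
#' @param max_violations allowed number of sub-threshold atom pairs.
#' @return `poses` with added columns `clash_violations`, `clash_ok`.
#' @export
clash_screen <- function(poses, static, mobile, min_dist = 2.5,
                         max_violations = 5) {
  xyz_s <- coords(static)
  xyz_m0 <- coords(mobile)
  s2 <- rowSums(xyz_s^2)
  viol <- integer(nrow(poses))
  for (k in seq_len(nrow(poses))) {
    tr <- pose_transform(poses[k, ])
    xyz_m <- sweep(xyz_m0 %*% t(tr$R), 2, tr$t, `+`)
    d2 <- outer(s2, rowSums(xyz_m^2), `+`) - 2 * xyz_s %*% t(xyz_m)
    viol[k] <- sum(d2 < min_dist^2)
  }
  poses$clash_violations <- viol
  poses$clash_ok <- viol <= max_violations
  poses
}

#' Summarise perturbations relative to a seed pose
#'
#' Decomposes each pose's transform relative to the seed pose into the
#' sampler's natural coordinates: translation components along the seed
#' center axis and the two perpendicular directions, the axial (twist)
#' rotation angle about the center axis, and the tilt angle of the axis.
#' Used to verify that empirical SDs match the requested spec.
#'
#' @param poses pose manifest tibble.
#' @param seed_pose the seed pose the manifest was sampled from.
#' @param static,mobile the two domains (reference frames).
#' @return tibble with columns id, d_axial, d_perp1, d_perp2 (A),
#'   axial_angle, tilt_angle (degrees).
#' @export
recover_perturbations <- function(poses, seed_pose, static, mobile) {
  cen_s <- heavy_centroid(static)
  cen_m <- posed_centroid(mobile, seed_pose)
  u <- vunit(cen_m - cen_s)
  P <- orthonormal_complement(u)
  tr0 <- pose_transform(seed_pose)
  out <- vector("list", nrow(poses))
  for (k in seq_len(nrow(poses))) {
    tr <- pose_transform(poses[k, ])
    dt <- posed_centroid(mobile, poses[k, ]) - cen_m
    Rd <- tr$R %*% t(tr0$R)
    out[[k]] <- tibble::tibble(
      id = poses$id[k],
      d_axial = sum(dt * u),
      d_perp1 = sum(dt * P[, 1]),
      d_perp2 = sum(dt * P[, 2]),
      axial_angle = twist_angle(Rd, u),
      tilt_angle = rad2deg(acos(pmin(1, pmax(-1, sum(u * (Rd %*% u))))))
    )
  }
  dplyr::bind_rows(out)
}

#' Write / read a pose manifest TSV
#'
#' @param poses pose manifest tibble.
#' @param path TSV path.
#' @return the manifest (invisibly for write).
#' @export
write_pose_manifest <- function(poses, path) {
  readr::write_tsv(poses, path)
  invisible(poses)
}

#' @rdname write_pose_manifest
#' @export
read_pose_manifest <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
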