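# Low-level rigid-body and internal-coordinate geometry shared by the
# structure builders, pose sampler and superposition metrics. All coordinates
# are in angstroms, angles in degrees unless a name says otherwise.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into [-180, 180)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into the half-open interval \[-180, 180).
#' @export
wrap_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  a / n
}

#' Dihedral angle of four points
#'
#' Signed torsion angle about the b-c axis using the standard IUPAC sign
#' convention (cis = 0, trans = 180/-180).
#'
#' @param a,b,c,d numeric 3-vectors.
#' @return angle in degrees in \[-180, 180).
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  wrap_angle(-rad2deg(atan2(sum(m1 * n2), sum(n1 * n2))))
}

# Vectorised dihedral over an ensemble: xyz is n_frames x 3N, ia..id are atom
# indices (1-based). Returns a vector of length n_frames, degrees.
dihedral_series <- function(xyz, ia, ib, ic, id) {
  col3 <- function(i) xyz[, (3 * i - 2):(3 * i), drop = FALSE]
  A <- col3(ia); B <- col3(ib); C <- col3(ic); D <- col3(id)
  b1 <- B - A
  b2 <- C - B
  b3 <- D - C
  cross_rows <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  n1 <- cross_rows(b1, b2)
  n2 <- cross_rows(b2, b3)
  b2u <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross_rows(n1, b2u)
  wrap_angle(-rad2deg(atan2(rowSums(m1 * n2), rowSums(n1 * n2))))
}

# NeRF placement: position atom D bonded to C, given upstream atoms A-B-C,
# the C-D bond length (angstroms), the B-C-D angle and the A-B-C-D dihedral
# (degrees). Satisfies dihedral(A, B, C, place_atom(...)) == dihedral.
place_atom <- function(a, b, c, length, angle, dihedral) {
  th <- deg2rad(angle)
  ch <- deg2rad(dihedral)
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d_local <- length * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis numeric 3-vector (normalised internally).
#' @param angle rotation angle in degrees (right-handed about `axis`).
#' @return 3x3 rotation matrix that multiplies column vectors.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- vunit(axis)
  th <- deg2rad(angle)
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, u[3], -u[2],
                 -u[3], 0, u[1],
                 u[2], -u[1], 0), 3, 3)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

#' Optimal superposition rotation (Kabsch)
#'
#' Least-squares rotation aligning the rows of `moving` onto the rows of
#' `target` after both are centred. Proper rotation (det = +1) guaranteed.
#'
#' @param moving,target n x 3 coordinate matrices with matched rows.
#' @return list with `rotation` (3x3, applied as `x %*% t(R)` to row
#'   vectors), `center_moving`, `center_target`.
#' @export
kabsch <- function(moving, target) {
  stopifnot(nrow(moving) == nrow(target), ncol(moving) == 3, ncol(target) == 3)
  if (nrow(moving) < 3) stop("need at least 3 atoms for superposition")
  cm <- colMeans(moving)
  ct <- colMeans(target)
  P <- sweep(moving, 2, cm)
  Q <- sweep(target, 2, ct)
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = R, center_moving = cm, center_target = ct)
}

# Apply a kabsch() fit to an n x 3 matrix.
apply_fit <- function(xyz, fit) {
  sweep(sweep(xyz, 2, fit$center_moving) %*% t(fit$rotation), 2,
        fit$center_target, `+`)
}

#' Root-mean-square deviation of matched coordinates
#'
#' @param a,b n x 3 coordinate matrices.
#' @param fit if `TRUE`, superpose `a` onto `b` (Kabsch) first.
#' @return RMSD in angstroms.
#' @export
rmsd <- function(a, b, fit = FALSE) {
  stopifnot(nrow(a) == nrow(b))
  if (fit) a <- apply_fit(a, kabsch(a, b))
  sqrt(mean(rowSums((a - b)^2)))
}

# Rotation matrix -> unit quaternion (w, x, y, z).
rotation_to_quaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

#' Twist component of a rotation about a given axis
#'
#' Swing-twist decomposition: writes the rotation as (swing about an axis
#' perpendicular to `axis`) composed with (twist about `axis`) and returns
#' the signed twist angle. Used to recover the axial rotation of a sampled
#' pose from its full transform.
#'
#' @param R 3x3 rotation matrix.
#' @param axis 3-vector twist axis.
#' @return signed twist angle in degrees in \[-180, 180).
#' @export
twist_angle <- function(R, axis) {
  u <- vunit(axis)
  q <- rotation_to_quaternion(R)
  proj <- sum(q[2:4] * u)
  wrap_angle(rad2deg(2 * atan2(proj, q[1])))
}
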