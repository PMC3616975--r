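# Seed placement and the Gaussian rigid-body sampler.

test_that("seed placement hits the requested contact gap", {
  for (gap in c(4, 10)) {
    p <- seed_placement(fx_static, fx_mobile, 7:9, 107:109,
                        contact_gap = gap)
    posed <- apply_pose(fx_mobile, p)
    d2 <- outer(rowSums(coords(fx_static)^2), rowSums(coords(posed)^2), `+`) -
      2 * coords(fx_static) %*% t(coords(posed))
    expect_lt(abs(sqrt(min(d2)) - gap), 0.1)
  }
})

test_that("seed placement puts patch and domain centroids on one line", {
  p <- seed_placement(fx_static, fx_mobile, 7:9, 107:109)
  posed <- apply_pose(fx_mobile, p)
  patch_s <- colMeans(coords(select_atoms(fx_static, resno = 7:9)))
  patch_m <- colMeans(coords(select_atoms(posed, resno = 107:109)))
  cen_s <- colMeans(coords(fx_static))
  cen_m <- colMeans(coords(posed))
  u <- (patch_s - cen_s) / sqrt(sum((patch_s - cen_s)^2))
  for (v in list(patch_m - cen_s, cen_m - cen_s)) {
    cosang <- sum(v * u) / sqrt(sum(v^2))
    expect_gt(abs(cosang), 1 - 1e-6)
  }
})

test_that("an all-zero perturbation spec returns the pose unchanged", {
  spec0 <- perturbation_spec(0, 0, 0, 0)
  poses <- sample_poses(fx_seed_pose, spec0, 5, seed = 1,
                        static = fx_static, mobile = fx_mobile)
  for (k in 1:5) {
    tr <- pose_transform(poses[k, ])
    tr0 <- pose_transform(fx_seed_pose)
    expect_equal(tr$R, tr0$R, tolerance = 1e-12)
    expect_equal(tr$t, tr0$t, tolerance = 1e-12)
  }
})

test_that("sampled rotations stay orthonormal with det +1", {
  poses <- sample_poses(fx_seed_pose, perturbation_spec(), 50, seed = 2,
                        static = fx_static, mobile = fx_mobile)
  for (k in seq_len(nrow(poses))) {
    R <- pose_transform(poses[k, ])$R
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-8)
    expect_equal(det(R), 1, tolerance = 1e-8)
  }
})

test_that("pose sampling is a pure function of its seed", {
  a <- sample_poses(fx_seed_pose, perturbation_spec(), 20, seed = 9,
                    static = fx_static, mobile = fx_mobile)
  b <- sample_poses(fx_seed_pose, perturbation_spec(), 20, seed = 9,
                    static = fx_static, mobile = fx_mobile)
  expect_identical(a, b)
  c <- sample_poses(fx_seed_pose, perturbation_spec(), 20, seed = 10,
                    static = fx_static, mobile = fx_mobile)
  expect_false(identical(a$tx, c$tx))
})

test_that("empirical perturbation SDs approach the spec values", {
  n <- 4000
  poses <- sample_poses(fx_seed_pose, perturbation_spec(), n, seed = 3,
                        static = fx_static, mobile = fx_mobile)
  rec <- recover_perturbations(poses, fx_seed_pose, fx_static, fx_mobile)
  expect_lt(abs(sd(rec$d_axial) / 3 - 1), 0.05)
  expect_lt(abs(sd(rec$d_perp1) / 8 - 1), 0.05)
  expect_lt(abs(sd(rec$d_perp2) / 8 - 1), 0.05)
  expect_lt(abs(sd(rec$axial_angle) / 8 - 1), 0.05)
  expect_lt(abs(sd(rec$tilt_angle) / (8 * sqrt(1 - 2 / pi)) - 1), 0.08)
  # tilt angles are magnitudes of N(0, 8): folded-normal SD = 8*sqrt(1-2/pi)
})

test_that("applying then inverting a pose transform restores coordinates", {
  poses <- sample_poses(fx_seed_pose, perturbation_spec(), 3, seed = 4,
                        static = fx_static, mobile = fx_mobile)
  tr <- pose_transform(poses[2, ])
  xyz <- coords(fx_mobile)
  fwd <- sweep(xyz %*% t(tr$R), 2, tr$t, `+`)
  back <- sweep(fwd, 2, tr$t) %*% tr$R
  expect_lt(max(abs(back - xyz)), 1e-6)
})

test_that("clash screen counts sub-threshold pairs like brute force", {
  sep <- make_two_domain_complex("AALAA", "AALAA", gap = 30)
  static <- sep$complex[sep$complex$chain == "A", ]
  mobile <- sep$complex[sep$complex$chain == "B", ]
  ok <- clash_screen(identity_pose(), static, mobile)
  expect_equal(ok$clash_violations, 0)
  expect_true(ok$clash_ok)

  # mobile moved onto the static domain: heavy overlap fails the screen
  onto <- pose_row(1L, diag(3),
                   colMeans(coords(static)) - colMeans(coords(mobile)))
  bad <- clash_screen(onto, static, mobile)
  expect_false(bad$clash_ok)

  # brute-force recount on a mildly overlapping pose
  nudge <- pose_row(2L, diag(3), c(-26, 0, 0))
  scr <- clash_screen(nudge, static, mobile, min_dist = 2.5)
  xa <- coords(static)
  xb <- coords(apply_pose(mobile, nudge))
  cnt <- 0
  for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb)))
    if (sqrt(sum((xa[i, ] - xb[j, ])^2)) < 2.5) cnt <- cnt + 1
  expect_equal(scr$clash_violations, cnt)
})
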