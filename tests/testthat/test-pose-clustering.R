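# Tethered RMSD, the pairwise matrix and NMRCLUST-style clustering.

mk_complex <- function(pose) {
  renumber(dplyr::bind_rows(fx_static, apply_pose(fx_mobile, pose)))
}
def_s <- domain_def("static", "A", 1, 15)
def_m <- domain_def("mobile", "B", 101, 115)

test_that("tethered RMSD is zero for identical and globally moved poses", {
  cx <- mk_complex(fx_seed_pose)
  expect_equal(tethered_rmsd(cx, cx, def_s, def_m), 0, tolerance = 1e-9)
  R <- rotation_about_axis(c(1, -1, 2), 73)
  moved <- transform_structure(cx, R, c(4, 5, -6))
  expect_lt(tethered_rmsd(cx, moved, def_s, def_m), 1e-9)
})

test_that("a uniform 5 A mobile shift gives tethered RMSD 5", {
  cx <- mk_complex(fx_seed_pose)
  shifted <- cx
  mask <- shifted$chain == "B"
  shifted$x[mask] <- shifted$x[mask] + 3
  shifted$y[mask] <- shifted$y[mask] + 4
  expect_equal(tethered_rmsd(cx, shifted, def_s, def_m), 5,
               tolerance = 1e-9)
})

test_that("tethered RMSD is symmetric and matches pairwise recomputation", {
  poses <- sample_poses(fx_seed_pose, perturbation_spec(), 6, seed = 21,
                        static = fx_static, mobile = fx_mobile)
  dm <- pairwise_pose_rmsd(poses, fx_static, fx_mobile)
  expect_true(isSymmetric(dm$values))
  expect_true(all(diag(dm$values) == 0))
  for (pair in list(c(1, 4), c(2, 6), c(3, 5))) {
    expect_equal(
      dm$values[pair[1], pair[2]],
      tethered_rmsd(mk_complex(poses[pair[1], ]),
                    mk_complex(poses[pair[2], ]), def_s, def_m),
      tolerance = 1e-9)
    expect_equal(dm$values[pair[1], pair[2]], dm$values[pair[2], pair[1]],
                 tolerance = 1e-9)
  }
  # duplicated pose gives a zero entry
  dup <- dplyr::bind_rows(poses, poses[1, ])
  dup$id <- seq_len(nrow(dup))
  dm2 <- pairwise_pose_rmsd(dup, fx_static, fx_mobile)
  expect_lt(dm2$values[1, 7], 1e-9)
})

test_that("Kabsch superposition attains the brute-force minimum RMSD", {
  set.seed(99)
  for (rep in 1:4) {
    a <- matrix(stats::rnorm(30, sd = 4), ncol = 3)
    R <- rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, 180))
    b <- sweep(a %*% t(R), 2, stats::rnorm(3, sd = 5), `+`) +
      matrix(stats::rnorm(30, sd = 0.3), ncol = 3)
    ours <- rmsd(a, b, fit = TRUE)
    expect_equal(ours, bf_min_rmsd(a, b), tolerance = 1e-6)
  }
})

test_that("planted pose groups are recovered exactly", {
  pg <- make_pose_groups(3, 10, separation = 20, spread = 1, seed = 31)
  dm <- pairwise_pose_rmsd(pg, fx_static, fx_mobile)
  cl <- nmrclust(dm)
  expect_equal(length(unique(cl$labels$cluster)), 3)
  tab <- table(pg$true_group, cl$labels$cluster)
  expect_true(all(rowSums(tab > 0) == 1))  # each true group -> one cluster
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("identical poses collapse to a single cluster", {
  pg <- make_pose_groups(1, 8, separation = 20, spread = 1e-9, seed = 3)
  dm <- pairwise_pose_rmsd(pg, fx_static, fx_mobile)
  cl <- nmrclust(dm)
  expect_equal(length(unique(cl$labels$cluster)), 1)
})

test_that("representatives are medoids (brute-force argmin of mean distance)", {
  pg <- make_pose_groups(2, 12, separation = 25, spread = 2, seed = 41)
  dm <- pairwise_pose_rmsd(pg, fx_static, fx_mobile)
  cl <- nmrclust(dm)
  for (g in unique(cl$labels$cluster)) {
    members <- which(cl$labels$cluster == g)
    means <- vapply(members, function(m)
      mean(dm$values[m, setdiff(members, m)]), numeric(1))
    bf_medoid <- members[which.min(means)]
    rep_id <- cl$labels$pose_id[members[cl$labels$is_representative[members]]]
    expect_equal(rep_id, cl$labels$pose_id[bf_medoid])
  }
})

test_that("top clusters are ordered by size with spread as tie-break", {
  sizes <- c(9, 7, 7, 5, 4, 3, 2)
  pg <- dplyr::bind_rows(lapply(seq_along(sizes), function(g) {
    set.seed(100 + g)
    spread <- if (g == 2) 0.5 else if (g == 3) 2.0 else 1.0
    dplyr::bind_rows(lapply(seq_len(sizes[g]), function(m)
      pose_row(g * 100L + m, diag(3),
               c(0, g * 30, 0) + stats::rnorm(3, sd = spread / sqrt(3)))))
  }))
  dm <- pairwise_pose_rmsd(pg, fx_static, fx_mobile)
  cl <- nmrclust(dm)
  expect_equal(length(unique(cl$labels$cluster)), 7)
  top <- top_clusters(cl, 5)
  expect_equal(nrow(top), 5)
  expect_equal(top$size, sort(top$size, decreasing = TRUE))
  # the two size-7 groups: tighter spread ranks first
  tied <- top[top$size == 7, ]
  expect_equal(nrow(tied), 2)
  expect_lt(tied$spread[1], tied$spread[2])
  # brute-force ordering check
  ord <- order(-top$size, top$spread)
  expect_equal(ord, seq_len(nrow(top)))

  expect_warning(top_clusters(cl, 10), "only 7 clusters")
  expect_equal(nrow(top_clusters(cl, 1)), 1)
})
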