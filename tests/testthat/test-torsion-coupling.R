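# Mutual-information estimator, permutation null and site clustering.

test_that("plugin MI matches analytic values on discrete series", {
  # two equally occupied bins, identical series: MI = ln 2
  x <- rep(c(-60, 180), 500)
  expect_equal(pair_mutual_information(x, x), log(2), tolerance = 1e-12)
  # k equally occupied bins: MI(a, a) = ln k
  k <- 4
  xk <- rep(c(-150, -60, 30, 120), 250)
  expect_equal(pair_mutual_information(xk, xk), log(k), tolerance = 1e-12)
  # invariance under bin relabeling (shift every angle by one bin width)
  y <- rep(c(-60, 180), 500)
  expect_equal(pair_mutual_information(x, y),
               pair_mutual_information(x, wrap_angle(y + 15)),
               tolerance = 1e-12)
  expect_error(pair_mutual_information(x, x[-1]), "different lengths")
})

test_that("MI of a sampled 2x2 joint table recovers the closed form within 3 SE", {
  joint <- matrix(c(0.4, 0.1, 0.1, 0.4), 2)
  # closed-form MI computed directly from the table
  pr <- rowSums(joint); pc <- colSums(joint)
  analytic <- sum(joint * log(joint / outer(pr, pc)))
  n <- 50000
  set.seed(123)
  cell <- sample.int(4, n, replace = TRUE, prob = as.vector(joint))
  wells <- c(-60, 180)
  a <- wells[ifelse(cell %in% c(1, 3), 1, 2)]
  b <- wells[ifelse(cell %in% c(1, 2), 1, 2)]
  est <- pair_mutual_information(a, b)
  # delta-method SE of the plugin estimator
  terms <- log(joint / outer(pr, pc))
  se <- sqrt((sum(joint * terms^2) - analytic^2) / n)
  expect_lt(abs(est - analytic), 3 * se + 2 / n)
})

test_that("the permutation null separates coupled from independent pairs", {
  set.seed(77)
  n <- 1200
  wells <- c(-60, 180)
  state <- sample.int(2, n, replace = TRUE)
  coupled_b <- ifelse(stats::runif(n) < 0.9, state, 3 - state)
  a <- wells[state] + stats::rnorm(n, sd = 5)
  b <- wells[coupled_b] + stats::rnorm(n, sd = 5)
  indep <- wells[sample.int(2, n, replace = TRUE)] + stats::rnorm(n, sd = 5)

  r_c <- pair_null(a, b, n_bins = 24, n_permutations = 100)
  expect_gt(r_c$mi, r_c$null_q95)
  r_i <- pair_null(a, indep, n_bins = 24, n_permutations = 100)
  expect_lt(r_i$mi, 0.05)
})

test_that("coupling_null is deterministic under a fixed seed", {
  ens <- make_rotamer_ensemble(3, n_frames = 100, seed = 2)
  tor <- extract_torsions(ens, torsions = "chi1")
  n1 <- coupling_null(tor, n_permutations = 60, seed = 5)
  n2 <- coupling_null(tor, n_permutations = 60, seed = 5)
  expect_identical(n1, n2)
  expect_error(coupling_null(tor, n_permutations = 10, seed = 1),
               "at least 50")
})

test_that("the coupling matrix finds a planted coupled pair as its argmax", {
  joint <- matrix(c(0.4, 0.1, 0.1, 0.4), 2)
  ens <- make_rotamer_ensemble(6, list(list(i = 2, j = 5, joint = joint)),
                               n_frames = 400, seed = 7)
  cm <- residue_coupling_matrix(extract_torsions(ens), seed = 11)
  peak <- which(cm$values == max(cm$values), arr.ind = TRUE)[1, ]
  expect_setequal(cm$residues[peak], c("A|2|", "A|5|"))
  expect_true(isSymmetric(cm$values))
  expect_true(all(diag(cm$values) == 0))
  # masked (non-significant) entries are exactly zero
  expect_true(all(cm$values[!cm$mask] == 0))
})

test_that("an all-independent ensemble yields a mostly-zero matrix", {
  ens <- make_rotamer_ensemble(8, n_frames = 400, seed = 13)
  cm <- residue_coupling_matrix(extract_torsions(ens), seed = 17)
  off <- cm$values[upper.tri(cm$values)]
  expect_gte(mean(off == 0), 0.95)
})

test_that("residue input order does not change the couplings", {
  joint <- matrix(c(0.45, 0.05, 0.05, 0.45), 2)
  ens <- make_rotamer_ensemble(4, list(list(i = 1, j = 4, joint = joint)),
                               n_frames = 300, seed = 19)
  tor <- extract_torsions(ens)
  cm1 <- residue_coupling_matrix(tor, seed = 23)
  cm2 <- residue_coupling_matrix(tor[rev(seq_len(nrow(tor))), ], seed = 23)
  ord <- match(cm1$residues, cm2$residues)
  expect_equal(cm2$values[ord, ord], cm1$values, tolerance = 1e-9)
})

test_that("site clustering recovers planted coupled blocks", {
  joint <- matrix(c(0.45, 0.05, 0.05, 0.45), 2)
  ens <- make_rotamer_ensemble(
    8, list(list(i = 1, j = 2, joint = joint),
            list(i = 5, j = 6, joint = joint)),
    n_frames = 500, seed = 29)
  cm <- residue_coupling_matrix(extract_torsions(ens), seed = 31)
  sites <- cluster_sites(cm, min_coupling = 0.1)
  expect_equal(nrow(sites), 2)
  members <- lapply(sites$residues, sort)
  expect_true(list(c("A|1|", "A|2|")) %in% members ||
                identical(members[[1]], c("A|1|", "A|2|")) ||
                identical(members[[2]], c("A|1|", "A|2|")))
  expect_setequal(unlist(members), c("A|1|", "A|2|", "A|5|", "A|6|"))

  # a single coupled pair gives a single 2-residue group
  ens1 <- make_rotamer_ensemble(5, list(list(i = 2, j = 4, joint = joint)),
                                n_frames = 400, seed = 37)
  cm1 <- residue_coupling_matrix(extract_torsions(ens1), seed = 41)
  sites1 <- cluster_sites(cm1, min_coupling = 0.1)
  expect_equal(nrow(sites1), 1)
  expect_setequal(sites1$residues[[1]], c("A|2|", "A|4|"))
})

test_that("an all-zero matrix clusters to nothing", {
  cm <- structure(list(residues = c("A|1|", "A|2|", "A|3|"),
                       values = matrix(0, 3, 3),
                       mask = matrix(FALSE, 3, 3),
                       n_bins = 24, n_permutations = 100, seed = 1),
                  class = "td_coupling")
  expect_equal(nrow(cluster_sites(cm)), 0)
})

test_that("the exported network edge list mirrors the significant couplings", {
  joint <- matrix(c(0.45, 0.05, 0.05, 0.45), 2)
  ens <- make_rotamer_ensemble(6, list(list(i = 1, j = 2, joint = joint),
                                       list(i = 3, j = 4, joint = joint),
                                       list(i = 5, j = 6, joint = joint)),
                               n_frames = 500, seed = 43)
  cm <- residue_coupling_matrix(extract_torsions(ens), seed = 47)
  f <- tempfile(fileext = ".tsv")
  edges <- export_network(cm, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  sig <- tidy(cm)
  sig <- sig[sig$significant, ]
  expect_equal(nrow(back), nrow(sig))
  expect_gte(nrow(back), 3)
  merged <- merge(back, sig, by = c("residue_i", "residue_j"))
  expect_equal(merged$weight, merged$coupling, tolerance = 1e-9)

  # empty matrix -> header-only file
  cm0 <- structure(list(residues = c("A|1|", "A|2|"),
                        values = matrix(0, 2, 2),
                        mask = matrix(FALSE, 2, 2),
                        n_bins = 24, n_permutations = 100, seed = 1),
                   class = "td_coupling")
  f0 <- tempfile(fileext = ".tsv")
  export_network(cm0, f0)
  expect_equal(length(readLines(f0)), 1)
})
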