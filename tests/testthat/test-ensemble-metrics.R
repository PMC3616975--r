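# Superposition, RMSF, segment RMSD series, distance monitors, ranking.

helix12 <- make_helix_domain(strrep("A", 12))
dom_core <- domain_def("core", "A", 1, 6)
dom_tail <- domain_def("tail", "A", 7, 12)

test_that("superposing globally rotated copies collapses them onto frame 1", {
  n <- 5
  xyz <- matrix(0, n, 3 * nrow(helix12))
  set.seed(8)
  for (k in seq_len(n)) {
    R <- rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, 180))
    moved <- transform_structure(helix12, R, stats::rnorm(3, sd = 10))
    xyz[k, ] <- as.vector(t(coords(moved)))
  }
  ens <- new_ensemble(helix12, xyz)
  fitted <- superpose_ensemble(ens, fit_domain = NULL, atoms = "CA")
  for (k in 2:n)
    expect_lt(max(abs(fitted$xyz[k, ] - fitted$xyz[1, ])), 1e-6)
  # idempotence
  fitted2 <- superpose_ensemble(fitted, fit_domain = NULL, atoms = "CA")
  expect_equal(fitted2$xyz, fitted$xyz, tolerance = 1e-9)
})

test_that("fitted RMSD equals the brute-force minimised RMSD", {
  ens <- make_jitter_ensemble(helix12, 0.8, 3, seed = 14)
  idx <- which(ens$atoms$name == "CA")
  f1 <- matrix(ens$xyz[1, ], ncol = 3, byrow = TRUE)[idx, ]
  f2 <- matrix(ens$xyz[2, ], ncol = 3, byrow = TRUE)[idx, ]
  expect_equal(rmsd(f2, f1, fit = TRUE), bf_min_rmsd(f2, f1),
               tolerance = 1e-6)
})

test_that("a static ensemble has an exactly zero RMSF profile", {
  ens <- make_jitter_ensemble(helix12, 0, 4, seed = 1)
  prof <- rmsf(ens, dom_core, dom_tail)
  expect_true(all(prof$rmsf == 0))
  expect_error(rmsf(make_jitter_ensemble(helix12, 0, 1, seed = 1),
                    dom_core, dom_tail),
               "at least 2 frames")
})

test_that("RMSF recovers the injected jitter amplitude as sigma*sqrt(3)", {
  sig <- stats::setNames(c(rep(0, 6), rep(1, 6)), 1:12)
  ens <- make_jitter_ensemble(helix12, sig, 500, seed = 9)
  prof <- rmsf(ens, dom_core, dom_tail)
  expect_lt(abs(mean_rmsf(prof) / sqrt(3) - 1), 0.05)
  # doubling sigma doubles the RMSF
  ens2 <- make_jitter_ensemble(helix12, 2 * sig, 500, seed = 9)
  prof2 <- rmsf(ens2, dom_core, dom_tail)
  expect_lt(abs(mean_rmsf(prof2) / (2 * mean_rmsf(prof)) - 1), 0.05)
})

test_that("RMSF is invariant under a global rigid motion of every frame", {
  sig <- stats::setNames(c(rep(0, 6), rep(0.8, 6)), 1:12)
  ens <- make_jitter_ensemble(helix12, sig, 60, seed = 10)
  R <- rotation_about_axis(c(2, 1, -1), 50)
  moved <- ens
  for (k in seq_len(n_frames(ens))) {
    fr <- matrix(ens$xyz[k, ], ncol = 3, byrow = TRUE)
    moved$xyz[k, ] <- as.vector(t(sweep(fr %*% t(R), 2, c(3, -4, 5), `+`)))
  }
  expect_equal(rmsf(moved, dom_core, dom_tail)$rmsf,
               rmsf(ens, dom_core, dom_tail)$rmsf, tolerance = 1e-6)
})

test_that("segment RMSD series detects a uniform shift exactly", {
  ens <- make_jitter_ensemble(helix12, 0, 3, seed = 1)
  # shift the tail of frame 2 by (0, 3, 0)
  tail_atoms <- which(ens$atoms$resno >= 7)
  ens$xyz[2, 3 * tail_atoms - 1] <- ens$xyz[2, 3 * tail_atoms - 1] + 3
  sr <- segment_rmsd_series(ens, fit_domain = dom_core,
                            measure_domain = dom_tail)
  expect_equal(sr$value, c(0, 3, 0), tolerance = 1e-9)
  # invariance under global motion of whole frames
  R <- rotation_about_axis(c(1, 1, 1), 66)
  for (k in 1:3) {
    fr <- matrix(ens$xyz[k, ], ncol = 3, byrow = TRUE)
    ens$xyz[k, ] <- as.vector(t(sweep(fr %*% t(R), 2, c(9, 9, 9), `+`)))
  }
  sr2 <- segment_rmsd_series(ens, fit_domain = dom_core,
                             measure_domain = dom_tail)
  expect_equal(sr2$value, sr$value, tolerance = 1e-6)
})

test_that("distance monitors track centroid and CA distances", {
  ens <- make_jitter_ensemble(helix12, 0, 3, seed = 1)
  s <- distance_series(ens, list(resno = 2), list(resno = 9),
                       mode = "centroid")
  expect_equal(length(unique(round(s$value, 9))), 1)  # constant ensemble
  # brute-force centroid check on frame 1
  fr <- frame_structure(ens, 1)
  g1 <- colMeans(coords(fr[fr$resno == 2, ]))
  g2 <- colMeans(coords(fr[fr$resno == 9, ]))
  expect_equal(s$value[1], sqrt(sum((g1 - g2)^2)), tolerance = 1e-9)

  # two single atoms exactly 5.8 A apart (a stacked-ring geometry monitor)
  pair <- renumber(dplyr::bind_rows(
    one_atom("CZ", "PHE", "C", c(0, 0, 0), resno = 1L),
    one_atom("CZ", "PHE", "C", c(5.8, 0, 0), resno = 2L)))
  ens2 <- new_ensemble(pair, matrix(as.vector(t(coords(pair))), 1))
  s2 <- distance_series(ens2, list(resno = 1), list(resno = 2),
                        mode = "centroid")
  expect_equal(s2$value, 5.8, tolerance = 1e-12)
})

test_that("the ranking table orders models by interaction energy and zeroes an empty interface", {
  cx <- make_two_domain_complex("AAKAA", "AAEAA",
    features = list(list(kind = "ionic_pair", res_a = 3, res_b = 3,
                         distance = 4.5)))
  one_frame <- function(s) new_ensemble(s, matrix(as.vector(t(coords(s))), 1))
  bound <- list(label = "bound", ensemble = one_frame(cx$complex),
                static = cx$domain_a, mobile = cx$domain_b, helix = NULL)
  # far enough that even the monopole-monopole Coulomb tail is negligible
  apart_cx <- cx$complex
  mask <- apart_cx$chain == "B"
  apart_cx$x[mask] <- apart_cx$x[mask] + 10000
  apart <- list(label = "apart", ensemble = one_frame(apart_cx),
                static = cx$domain_a, mobile = cx$domain_b, helix = NULL)
  rk <- ranking_table(list(apart, bound), n_points = 240)
  expect_equal(rk$model, c("bound", "apart"))  # ascending e_bind
  expect_equal(rk$e_bind_sd, c(0, 0))          # single-frame ensembles
  arow <- rk[rk$model == "apart", ]
  expect_lt(abs(arow$e_bind_mean), 0.05)
  expect_lt(abs(arow$bsa), 10)
  expect_equal(arow$n_ionic + arow$n_hydrophobic, 0)
  expect_identical(names(rk), c("model", "e_bind_mean", "e_bind_sd",
                                "pk_rmsf", "bsa", "n_ionic",
                                "n_hydrophobic", "contacts", "kh_rmsf"))
  f <- tempfile(fileext = ".tsv")
  write_ranking_tsv(rk, f)
  hdr <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_identical(hdr, c("Type", "Interaction Energy (kcal/mol)",
                          "PK_RMSF (A)", "BSA(A^2)", "Contacts",
                          "KH_RMSF (A)"))
})
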