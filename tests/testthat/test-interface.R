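# SASA/BSA quadrature and the contact detectors.

test_that("single-sphere SASA matches the analytic area within 1%", {
  a <- one_atom("C", "ALA", "C", c(0, 0, 0))
  area <- sasa(a)
  expect_lt(abs(area / (4 * pi * (1.70 + 1.4)^2) - 1), 0.01)
})

test_that("distant atoms have additive SASA", {
  two <- dplyr::bind_rows(one_atom("C", "ALA", "C", c(0, 0, 0)),
                          one_atom("O", "ALA", "O", c(100, 0, 0)))
  two$serial <- 1:2
  areas <- sasa(two)
  expect_equal(sum(areas),
               4 * pi * (1.70 + 1.4)^2 + 4 * pi * (1.52 + 1.4)^2,
               tolerance = 0.01 * 4 * pi * 3.1^2)
})

test_that("overlapping equal spheres match a dense quadrature oracle within 2%", {
  for (d in c(2.0, 3.0)) {
    two <- renumber(dplyr::bind_rows(
      one_atom("C", "ALA", "C", c(0, 0, 0)),
      one_atom("C", "ALA", "C", c(d, 0, 0), resno = 2L)))
    areas <- sasa(two)
    re <- 1.70 + 1.4
    oracle <- bf_two_sphere_area(c(0, 0, 0), re, c(d, 0, 0), re)
    expect_lt(abs(areas[1] / oracle - 1), 0.02)
  }
})

test_that("unknown elements fall back to the default radius with a warning", {
  odd <- one_atom("XX", "ALA", "ZZ", c(0, 0, 0))
  expect_warning(area <- sasa(odd), "unknown element")
  expect_lt(abs(area / (4 * pi * (1.70 + 1.4)^2) - 1), 0.01)
})

test_that("buried surface area behaves definitionally", {
  far <- make_two_domain_complex("AALAA", "AALAA", gap = 100)
  expect_lt(abs(buried_surface_area(far$complex, far$domain_a,
                                    far$domain_b)), 10)
  cx <- make_two_domain_complex("AALAA", "AALAA",
    features = list(list(kind = "hydrophobic_pair", res_a = 3, res_b = 3,
                         distance = 4.5)))
  b1 <- buried_surface_area(cx$complex, cx$domain_a, cx$domain_b)
  b2 <- buried_surface_area(cx$complex, cx$domain_a, cx$domain_b)
  expect_identical(b1, b2)  # deterministic quadrature
  expect_gt(b1, 50)
  # definitional recomputation from three SASA calls
  a <- cx$complex[cx$complex$chain == "A", ]
  b <- cx$complex[cx$complex$chain == "B", ]
  expect_equal(b1, sum(sasa(a)) + sum(sasa(b)) - sum(sasa(cx$complex)),
               tolerance = 1e-9)
  # invariance under global rigid motion, up to quadrature noise (the
  # sphere grid is fixed in the lab frame)
  moved <- transform_structure(cx$complex,
                               rotation_about_axis(c(1, 2, -1), 35),
                               c(10, -3, 7))
  expect_equal(buried_surface_area(moved, cx$domain_a, cx$domain_b), b1,
               tolerance = 0.02)
  # overlapping domains error
  expect_error(buried_surface_area(cx$complex, cx$domain_a,
                                   domain_def("B2", "A", 1, 5)),
               "overlap")
})

test_that("hydrophobic contacts respect the 5 A boundary and residue class", {
  near <- make_two_domain_complex("GGLGG", "GGLGG",
    features = list(list(kind = "hydrophobic_pair", res_a = 3, res_b = 3,
                         distance = 4.9)))
  expect_equal(nrow(hydrophobic_contacts(near$complex, near$domain_a,
                                         near$domain_b)), 1)
  beyond <- make_two_domain_complex("GGLGG", "GGLGG",
    features = list(list(kind = "hydrophobic_pair", res_a = 3, res_b = 3,
                         distance = 5.1)))
  expect_equal(nrow(hydrophobic_contacts(beyond$complex, beyond$domain_a,
                                         beyond$domain_b)), 0)
  # hydrophobic-vs-serine apposition does not count
  ser <- make_two_domain_complex("GGLGG", "GGSGG", gap = 7)
  expect_equal(nrow(hydrophobic_contacts(ser$complex, ser$domain_a,
                                         ser$domain_b)), 0)
})

test_that("contact lists equal all-pairs brute force on a planted fixture", {
  cx <- make_two_domain_complex("ALKLA", "ELALE",
    features = list(list(kind = "hydrophobic_pair", res_a = 2, res_b = 3,
                         distance = 4.0)))
  found <- hydrophobic_contacts(cx$complex, cx$domain_a, cx$domain_b)
  cls <- residue_classes()
  hydro <- cls$resname[cls$hydrophobic]
  bf <- bf_contacts(cx$complex, "A", "B", 5, hydro,
                    function(d) !(d$name %in% c("N", "CA", "C", "O", "OXT")))
  got <- paste(sub("A\\|(\\d+)\\|", "\\1", found$residue_a),
               sub("B\\|(\\d+)\\|", "\\1", found$residue_b))
  expect_setequal(got, bf)
  # atom-order shuffling does not change the contact set
  shuf <- cx$complex[sample(nrow(cx$complex)), ]
  found2 <- hydrophobic_contacts(shuf, cx$domain_a, cx$domain_b)
  expect_setequal(paste(found2$residue_a, found2$residue_b),
                  paste(found$residue_a, found$residue_b))
})

test_that("ionic contacts require opposite charges within the 6 A window", {
  cx <- make_two_domain_complex("AAKAA", "AAEAA",
    features = list(list(kind = "ionic_pair", res_a = 3, res_b = 3,
                         distance = 5.9)))
  found <- ionic_contacts(cx$complex, cx$domain_a, cx$domain_b)
  expect_equal(nrow(found), 1)
  expect_equal(found$sign_a * found$sign_b, -1L)
  # removing the glutamate abolishes the contact
  no_glu <- cx$complex[!(cx$complex$chain == "B" & cx$complex$resno == 3), ]
  expect_equal(nrow(ionic_contacts(no_glu, cx$domain_a, cx$domain_b)), 0)
  # like charges close together do not count
  kk <- make_two_domain_complex("AAKAA", "AARAA", gap = 8)
  expect_equal(nrow(ionic_contacts(kk$complex, kk$domain_a, kk$domain_b)), 0)
})

test_that("stacking pairs use ring centroids inside the 4.5-7.0 A window", {
  cx <- make_two_domain_complex("AAFAA", "AAFAA",
    features = list(list(kind = "stacking_pair", res_a = 3, res_b = 3,
                         distance = 5.8)))
  pairs <- stacking_pairs(cx$complex, cx$domain_a, cx$domain_b)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$centroid_distance, 5.8, tolerance = 0.05)
  far <- make_two_domain_complex("AAFAA", "AAFAA",
    features = list(list(kind = "stacking_pair", res_a = 3, res_b = 3,
                         distance = 7.5)))
  expect_equal(nrow(stacking_pairs(far$complex, far$domain_a,
                                   far$domain_b)), 0)
  # centroid = arithmetic mean of ring heavy atoms (brute force)
  ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  a3 <- cx$complex[cx$complex$chain == "A" & cx$complex$resno == 3 &
                     cx$complex$name %in% ring, ]
  b3 <- cx$complex[cx$complex$chain == "B" & cx$complex$resno == 3 &
                     cx$complex$name %in% ring, ]
  bf_d <- sqrt(sum((colMeans(cbind(a3$x, a3$y, a3$z)) -
                      colMeans(cbind(b3$x, b3$y, b3$z)))^2))
  expect_equal(pairs$centroid_distance, bf_d, tolerance = 1e-9)
})

test_that("salt bridges are the tight subset of ionic contacts", {
  close <- make_two_domain_complex("AAKAA", "AAEAA",
    features = list(list(kind = "ionic_pair", res_a = 3, res_b = 3,
                         distance = 3.5)))
  expect_equal(nrow(salt_bridges(close$complex, close$domain_a,
                                 close$domain_b)), 1)
  loose <- make_two_domain_complex("AAKAA", "AAEAA",
    features = list(list(kind = "ionic_pair", res_a = 3, res_b = 3,
                         distance = 5.5)))
  expect_equal(nrow(salt_bridges(loose$complex, loose$domain_a,
                                 loose$domain_b)), 0)
  expect_equal(nrow(ionic_contacts(loose$complex, loose$domain_a,
                                   loose$domain_b)), 1)
})
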