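# Shared fixtures and independent brute-force oracles. Everything here is
# generated in code; nothing is read from disk.

# Two small helical domains used across docking tests (built once per run).
fx_static <- make_helix_domain("AALKEFARLEAKVAE", chain = "A")
fx_mobile <- make_helix_domain("AELRVFAELKARFAE", chain = "B",
                               first_resno = 101L)

fx_seed_pose <- seed_placement(fx_static, fx_mobile,
                               site_static = 7:9, site_mobile = 107:109,
                               contact_gap = 4)

# --- independent oracles -------------------------------------------------

# Brute-force minimised RMSD: numerical optimisation over an axis-angle
# rotation + translation, several restarts. Independent of the Kabsch path.
bf_min_rmsd <- function(moving, target) {
  obj <- function(par) {
    ang <- sqrt(sum(par[1:3]^2))
    R <- if (ang < 1e-12) diag(3) else
      rotation_about_axis(par[1:3], ang * 180 / pi)
    sqrt(mean(rowSums((sweep(moving %*% t(R), 2, par[4:6], `+`) - target)^2)))
  }
  starts <- list(rep(0, 6), c(pi / 2, 0, 0, 0, 0, 0), c(0, pi, 0, 0, 0, 0),
                 c(1, 1, 1, 1, -1, 2), c(-2, 0.5, 1.5, -3, 2, 0))
  best <- Inf
  for (s in starts) {
    r <- stats::optim(s, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
    r <- stats::optim(r$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
    best <- min(best, r$value)
  }
  best
}

# All-pairs brute-force contact detection between two domains of a complex,
# with an arbitrary per-residue atom filter and residue-class predicate.
bf_contacts <- function(complex, chain_a, chain_b, cutoff, resnames,
                        atom_subset) {
  cls <- residue_classes()
  pick <- function(chain) {
    d <- complex[complex$chain == chain & complex$resname %in% resnames, ,
                 drop = FALSE]
    d[atom_subset(d), , drop = FALSE]
  }
  a <- pick(chain_a); b <- pick(chain_b)
  found <- character(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      dd <- sqrt(sum((unlist(a[i, c("x", "y", "z")]) -
                        unlist(b[j, c("x", "y", "z")]))^2))
      if (dd <= cutoff)
        found <- union(found, paste(a$resno[i], b$resno[j]))
    }
  }
  found
}

# Full pairwise nonbonded energy of an arbitrary atom set, written
# independently of interaction_energy() (same physical model, different
# code path: loops, explicit subtraction formula support).
bf_total_energy <- function(structure, dielectric = 4, k = 332.0636) {
  lj_tbl <- list(C = c(3.40, 0.086), N = c(3.25, 0.170),
                 O = c(2.96, 0.210), S = c(3.55, 0.250))
  q <- numeric(nrow(structure))
  for (i in seq_len(nrow(structure))) {
    rn <- structure$resname[i]; nm <- structure$name[i]
    if (rn == "ASP" && nm %in% c("OD1", "OD2")) q[i] <- -0.5
    if (rn == "GLU" && nm %in% c("OE1", "OE2")) q[i] <- -0.5
    if (rn == "LYS" && nm == "NZ") q[i] <- 1
    if (rn == "ARG" && nm %in% c("NE", "NH1", "NH2")) q[i] <- 1 / 3
  }
  e <- 0
  for (i in seq_len(nrow(structure) - 1)) {
    for (j in (i + 1):nrow(structure)) {
      r <- sqrt(sum((unlist(structure[i, c("x", "y", "z")]) -
                       unlist(structure[j, c("x", "y", "z")]))^2))
      e <- e + k * q[i] * q[j] / (dielectric * r)
      pi_ <- lj_tbl[[structure$element[i]]]
      pj_ <- lj_tbl[[structure$element[j]]]
      if (!is.null(pi_) && !is.null(pj_)) {
        s <- (pi_[1] + pj_[1]) / 2
        eps <- sqrt(pi_[2] * pj_[2])
        e <- e + 4 * eps * ((s / r)^12 - (s / r)^6)
      }
    }
  }
  e
}

# Dense-quadrature SASA oracle for a pair of spheres: area of sphere 1 not
# inside sphere 2, estimated with a very fine independent grid.
bf_two_sphere_area <- function(c1, r1, c2, r2, n = 200000) {
  set.seed(42)
  z <- stats::rnorm(n * 3)
  pts <- matrix(z, ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2))
  p <- sweep(pts * r1, 2, c1, `+`)
  frac <- mean(rowSums(sweep(p, 2, c2)^2) >= r2^2)
  4 * pi * r1^2 * frac
}

# Minimal single-atom structure helper for metric closed-form tests.
one_atom <- function(name, resname, element, pos, chain = "A", resno = 1L) {
  tibble::tibble(serial = 1L, name = name, altloc = "", resname = resname,
                 chain = chain, resno = as.integer(resno), insert = "",
                 x = pos[1], y = pos[2], z = pos[3], occupancy = 1,
                 element = element)
}

renumber <- function(complex) {
  complex$serial <- seq_len(nrow(complex))
  complex
}
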