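# Solvent-accessible surface area by Shrake-Rupley quadrature and the
# buried-surface-area interface metric derived from it.

#' Van der Waals radii for SASA
#'
#' Bondi-type heavy-atom radii, by element. Unknown elements fall back to
#' `default` with a warning.
#'
#' @return named numeric vector of radii (A).
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
    F = 1.47, CL = 1.75, BR = 1.85, SE = 1.90)
}

# Deterministic near-uniform sphere quadrature (Fibonacci spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Accessible area per heavy atom: each atom's sphere of radius
#' `r_vdw + probe` is sampled at `n_points` quadrature points and the
#' fraction not occluded by any neighbouring sphere contributes to its
#' area.
#'
#' @param structure an atom tibble.
#' @param probe probe (solvent) radius, A; 1.4 A approximates water.
#' @param n_points quadrature points per atom; 960 gives ~1% accuracy on a
#'   single sphere.
#' @param radii named per-element radius vector, see [vdw_radii()].
#' @param default_radius fallback for unknown elements (warned once).
#' @return numeric vector of per-atom areas, A^2; `sum()` gives the total.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960,
                 radii = vdw_radii(), default_radius = 1.70) {
  assert_structure(structure)
  xyz <- coords(structure)
  r <- unname(radii[structure$element])
  if (anyNA(r)) {
    warning(sprintf("unknown element(s) %s: using default radius %.2f A",
                    paste(unique(structure$element[is.na(r)]), collapse = ", "),
                    default_radius), call. = FALSE)
    r[is.na(r)] <- default_radius
  }
  re <- r + probe
  pts <- sphere_points(n_points)
  n <- nrow(xyz)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (re[i] + re)^2 & seq_len(n) != i)
    p_i <- sweep(pts * re[i], 2, xyz[i, ], `+`)
    if (length(nb) == 0) {
      frac <- 1
    } else {
      occluded <- rep(FALSE, n_points)
      for (j in nb) {
        occluded <- occluded |
          (rowSums(sweep(p_i, 2, xyz[j, ])^2) < re[j]^2)
        if (all(occluded)) break
      }
      frac <- mean(!occluded)
    }
    areas[i] <- 4 * pi * re[i]^2 * frac
  }
  areas
}

#' Buried surface area of a two-domain interface
#'
#' BSA = SASA(A alone) + SASA(B alone) - SASA(complex), non-negative up to
#' quadrature noise. Note this uses the solvent-accessible surface, so
#' absolute values are not comparable with molecular-surface programs; the
#' metric's role here is ranking poses of the same system.
#'
#' @param complex atom tibble containing both domains.
#' @param domain_a,domain_b [domain_def()] rows; they must not overlap.
#' @inheritParams sasa
#' @return BSA in A^2.
#' @export
buried_surface_area <- function(complex, domain_a, domain_b, probe = 1.4,
                                n_points = 960) {
  mask_a <- selection_mask(complex, domain_a, NULL, NULL, NULL)
  mask_b <- selection_mask(complex, domain_b, NULL, NULL, NULL)
  if (any(mask_a & mask_b))
    stop("domain definitions overlap", call. = FALSE)
  if (!any(mask_a) || !any(mask_b))
    stop("empty selection: a domain matches no atoms", call. = FALSE)
  a <- complex[mask_a, , drop = FALSE]
  b <- complex[mask_b, , drop = FALSE]
  ab <- complex[mask_a | mask_b, , drop = FALSE]
  sum(sasa(a, probe, n_points)) + sum(sasa(b, probe, n_points)) -
    sum(sasa(ab, probe, n_points))
}
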