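# Simplified pairwise nonbonded interaction energy between two domains.
#
# The binding energy follows E_bind = E_complex - E_A - E_B; because the
# energy model is a pairwise-additive sum of Coulomb and Lennard-Jones
# terms, the subtraction reduces exactly to the sum over cross-domain atom
# pairs, which is what is computed (and the identity is asserted by test).
# Parameters are a deliberately coarse, transparent set: unit formal
# charges spread evenly over the charged side-chain groups, generic
# per-element Lennard-Jones classes, and a screened-interior relative
# dielectric.

#' Coarse nonbonded parameter set
#'
#' @param dielectric relative dielectric constant (default 4, a common
#'   choice for screened protein interiors).
#' @param coulomb_k Coulomb constant in kcal*A/(mol*e^2).
#' @param lj per-element Lennard-Jones classes: data frame with element,
#'   sigma (A), epsilon (kcal/mol).
#' @return a `td_nonbonded_params` list.
#' @export
nonbonded_params <- function(dielectric = 4, coulomb_k = 332.0636,
                             lj = NULL) {
  if (is.null(lj)) {
    lj <- tibble::tibble(
      element = c("C", "N", "O", "S", "P", "H"),
      sigma = c(3.40, 3.25, 2.96, 3.55, 3.74, 2.50),
      epsilon = c(0.086, 0.170, 0.210, 0.250, 0.200, 0.015))
  }
  stopifnot(all(lj$sigma >= 0), all(lj$epsilon >= 0), dielectric > 0)
  structure(list(dielectric = dielectric, coulomb_k = coulomb_k, lj = lj),
            class = "td_nonbonded_params")
}

# Formal charge per atom: -1 spread over carboxylate oxygens (ASP, GLU),
# +1 on LYS NZ, +1 spread over ARG guanidinium nitrogens. HIS neutral.
assign_charges <- function(structure) {
  q <- numeric(nrow(structure))
  q[structure$resname == "ASP" & structure$name %in% c("OD1", "OD2")] <- -0.5
  q[structure$resname == "GLU" & structure$name %in% c("OE1", "OE2")] <- -0.5
  q[structure$resname == "LYS" & structure$name == "NZ"] <- 1
  q[structure$resname == "ARG" &
      structure$name %in% c("NE", "NH1", "NH2")] <- 1 / 3
  q
}

lj_lookup <- function(structure, params) {
  idx <- match(structure$element, params$lj$element)
  if (anyNA(idx)) {
    warning(sprintf("no LJ class for element(s) %s: treating as carbon",
                    paste(unique(structure$element[is.na(idx)]),
                          collapse = ", ")), call. = FALSE)
    idx[is.na(idx)] <- match("C", params$lj$element)
  }
  list(sigma = params$lj$sigma[idx], epsilon = params$lj$epsilon[idx])
}

#' Interdomain nonbonded interaction energy
#'
#' Exact sum over all cross-domain heavy-atom pairs of a screened Coulomb
#' term and a 12-6 Lennard-Jones term with Lorentz-Berthelot combination.
#' Equals E_complex - E_A - E_B for this pairwise-additive model.
#'
#' @param complex atom tibble with both domains.
#' @param domain_a,domain_b [domain_def()] rows.
#' @param params a [nonbonded_params()].
#' @return a one-row tibble: e_ele, e_vdw, e_bind (kcal/mol).
#' @export
interaction_energy <- function(complex, domain_a, domain_b,
                               params = nonbonded_params()) {
  stopifnot(inherits(params, "td_nonbonded_params"))
  doms <- split_domains(complex, domain_a, domain_b)
  xa <- coords(doms$a); xb <- coords(doms$b)
  r2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  r <- sqrt(pmax(r2, 0))
  if (min(r) < 0.5)
    stop(sprintf(
      "atom pair at %.2f A (< 0.5 A): severe clash, energies are meaningless",
      min(r)), call. = FALSE)
  qa <- assign_charges(doms$a); qb <- assign_charges(doms$b)
  e_ele <- params$coulomb_k / params$dielectric *
    sum(outer(qa, qb) / r)
  lja <- lj_lookup(doms$a, params); ljb <- lj_lookup(doms$b, params)
  sig <- outer(lja$sigma, ljb$sigma, `+`) / 2
  eps <- sqrt(outer(lja$epsilon, ljb$epsilon))
  sr6 <- (sig / r)^6
  e_vdw <- sum(4 * eps * (sr6^2 - sr6))
  tibble::tibble(e_ele = e_ele, e_vdw = e_vdw, e_bind = e_ele + e_vdw)
}
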