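---
title: "Methods: tether-constrained docking guided by torsional coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tether-constrained docking guided by torsional coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetherdock)
```

This vignette is the package's own account of the models and numerical
choices behind each pipeline stage, and of what the synthetic test beds do
and do not establish about real data.

## The problem

Two protein domains joined by a covalent linker — a kinase and its
pseudokinase regulator being the motivating case — form a transient
complex whose structure is unknown. The search space for rigid-body
docking is vastly reduced by two observations: (i) plausible interfaces
should connect *allosteric sites*, i.e. surface patches whose residues
show strong correlated torsional motions with the rest of their domain;
and (ii) the linker geometrically caps how far apart the two attachment
points can sit. The pipeline operationalises both: nominate sites from
torsion-coupling statistics, seed a pose joining them, sample locally,
filter by linker reach, cluster, and rank by interface quality.

## Torsion coupling (mutual information)

**Model.** For each residue we extract per-frame φ, ψ, ω and χ₁–χ₄
dihedrals from a conformational ensemble. Coupling between two torsions is
the plugin (histogram) mutual information of their discretised joint
distribution, in nats. Residue-level coupling sums, over all cross-residue
torsion pairs, the *excess* MI (observed minus permutation-null mean),
counting only pairs whose observed MI exceeds the null's 95th percentile.

**Binning.** Fixed-width bins of 15° (24 bins over [−180°, 180°)). A
fixed-width scheme is exactly reproducible, adequate for rotameric
side-chain statistics (wells sit ~120° apart, far wider than a bin), and
avoids the extra tuning of adaptive partitioning. The bin count is a
config parameter (`n_bins`).

**Significance.** The null permutes the frames of one series (100
permutations by default, at least 50 enforced) — this destroys temporal
co-variation while preserving both marginals, which is precisely the
independence hypothesis for the plugin estimator's positive bias. The
permuted series is chosen canonically (lexicographically larger label) and
each pair's permutation stream is seeded from the pair's identity plus the
global seed, so the matrix is invariant to the order residues are supplied
in and byte-identical across reruns. ω is excluded from coupling by
default (near-constant in trans peptides); constant series are skipped
since their MI is identically zero.

**Pooling.** Several independent simulation copies can be supplied as a
list of topology-matched ensembles; frames are concatenated after
validation. This treats the copies as one stationary sample, which is the
simplest defensible reading when copies differ only in their random seeds.

**Site grouping.** Average-linkage hierarchical clustering on the distance
`max(coupling) − coupling`, cut at the height corresponding to the
`min_coupling` threshold (default 0.1 nat); only multi-residue groups whose
mean internal coupling reaches the threshold are reported, largest first.
The 0.1 nat default is far above the corrected background (which is ~0 by
construction) yet well below a single strongly coupled rotamer pair
(ln 2 ≈ 0.69 nats maximum for two-state couplings).

## Pose seeding and Gaussian sampling

**Seed placement.** The mobile domain is rotated so its patch-outward axis
(patch centroid minus domain centroid) anti-aligns with the static one,
then slid along the patch-connecting line until the minimum interdomain
heavy-atom distance equals `contact_gap` (default 4 Å — van der Waals
contact plus slack for the absence of side-chain repacking). The slide is
solved by bisection to well under 0.1 Å. A warning (not an error) is
raised if a patch looks buried, using a directional exposure proxy: more
than 25% of the domain's atoms lying >3 Å beyond the patch centroid along
its outward axis.

**Perturbation.** Each sampled pose perturbs the *seed* pose (not a Markov
chain — the published scheme describes independent draws around a
predetermined configuration): translation N(0, 3 Å) along the line through
the two domain centers and N(0, 8 Å) along each of two perpendicular
directions; then rotation N(0, 8°) about the center axis; then a tilt of
that axis by N(0, 8°) about an axis drawn uniformly in the perpendicular
plane (the tilt-axis distribution is not specified anywhere authoritative;
uniform is the symmetric choice). Rotations act about the translated
mobile centroid so the translation components remain exactly Gaussian and
are recoverable from the final transform; the rotation decomposes back via
swing–twist. The draw order (axial translation, two perpendicular
translations, axial angle, tilt angle, tilt axis) is fixed for
determinism.

**Clash handling.** Instead of repacking side chains (out of scope), a
screen counts interdomain heavy-atom pairs closer than 2.5 Å and flags
poses with more than 5 violations; flagged poses are retained but marked,
and `strict_clash` drops them. Flagging preserves the sampler's geometry
for downstream statistics while still exposing physical plausibility.

## Tether filter

The linker-reach proxy is the Cα–Cα distance between the static domain's
C-terminal attachment residue and the mobile domain's N-terminal one,
compared against an inclusive cutoff (default 60 Å). Cα is the
conventional tether anchor; inclusivity matters only on a measure-zero
boundary and is documented and configurable. `linker_max_extension()`
offers the physical bound of 3.8 Å per linker residue (e.g. 87.4 Å for a
23-residue linker) as a sanity check on user cutoffs. The filter is
idempotent and monotone in the cutoff, and survivor counts are reported
rather than capped — any "keep at most N" policy is left to configuration.

## Pose clustering

The pose metric is tethered RMSD: Kabsch superposition over static-domain
Cα, then plain Cα RMSD over the mobile domain. Clustering is average
linkage over the full pairwise matrix. The published stopping rule we
emulate combines an average spread term with a cluster-count term; since
its exact normalisation constants are not restated anywhere we can cite,
both terms are linearly rescaled onto [1, n_steps] across the merge
trajectory and summed, and the step with the minimal sum is chosen (first
on ties). Cluster spread is the mean pairwise distance within multi-member
clusters (singletons excluded from the average). A degenerate all-equal
matrix short-circuits to a single cluster. Representatives are medoids —
the member minimising mean distance to the rest — and "top" clusters are
ordered by size, ties broken by smaller spread (ranking by mean
interaction energy instead is a documented alternative via the reports).

## Interface metrics

* **BSA** = SASA(A) + SASA(B) − SASA(complex), with Shrake–Rupley
  solvent-accessible areas (probe 1.4 Å, 960 Fibonacci-spiral points per
  atom, Bondi-type radii, heavy atoms only). Absolute values are *not*
  comparable with molecular-surface (e.g. MSMS) areas; the metric's role
  here is ranking poses of one system, which the monotone relationship
  preserves. The quadrature grid is fixed in the lab frame, so BSA is
  rotation-invariant only to ~1–2% (quadrature noise) — tests account for
  this.
* **Contacts.** Hydrophobic: pairs of hydrophobic residues (ALA, VAL,
  LEU, ILE, MET, PHE, TRP, PRO, TYR) with side-chain heavy atoms within
  5 Å. Ionic: oppositely charged residues (LYS/ARG/HIS vs ASP/GLU) with
  charged-group atoms within 6 Å; salt bridges are the subset within 4 Å
  (a conventional tight-contact threshold — the looser 6 Å window defines
  the panel's ionic count). π-stacking: aromatic ring centroids within
  4.5–7.0 Å. All cutoffs inclusive; each residue pair counted once (contact
  counts are residue-pair counts, not atom-pair counts). The
  classification table is user-overridable.
* **Energy.** E_ele = Σ k·qᵢqⱼ/(ε_r·rᵢⱼ) and E_vdw = Σ 4εᵢⱼ[(σᵢⱼ/r)¹² −
  (σᵢⱼ/r)⁶] over all cross-domain heavy-atom pairs, k = 332.0636
  kcal·Å/(mol·e²), Lorentz–Berthelot combination, no distance cutoff (the
  exact sum is affordable at this scale). Charges are a transparent formal
  set: −0.5 on each carboxylate oxygen, +1 on lysine NZ, +1/3 on each
  arginine guanidinium nitrogen, histidine neutral; LJ parameters are
  generic per-element classes. ε_r defaults to 4, a common effective
  dielectric for screened protein interiors (the appropriate value for a
  given system is genuinely uncertain; it scales E_ele uniformly and so
  does not affect pose ranking within one configuration). Because the
  model is pairwise additive, E_complex − E_A − E_B reduces *exactly* to
  the cross-domain sum; the identity is asserted against an independent
  brute-force total-energy routine in the tests. Pairs closer than 0.5 Å
  are an error — such a pose is physically meaningless and should have
  been screened.

## Ensemble metrics and ranking

RMSF is computed about the *time-mean* position (the standard choice;
first-frame referencing mixes displacement into fluctuation) after Kabsch
fitting every frame to frame 1 over the fit selection. The panel's
PK-style RMSF fits on the static (kinase) domain and measures the mobile
domain; the helix-RMSF column measures a stated helix range instead.
Segment RMSD series fit each frame to a reference over one selection and
measure another, and distance monitors support centroid / minimum /
Cα–Cα modes (ring-atom centroids for stacking monitors). The ranking
table averages energy, BSA and contact counts over frames (counts rounded
half-up to match an integer panel), reports mean ± SD for the energy, and
sorts ascending by mean binding energy — most favourable first — since
that is the panel's primary quantitative column.

## Synthetic generators: what they emulate

* `make_helix_domain()` builds ideal-geometry peptides (standard bond
  lengths/angles, NeRF placement) at stated (φ, ψ), with idealised
  side-chain rotamers — enough realism for class-based contact metrics and
  torsion statistics, none for packing or electrostrictive detail.
* `make_rotamer_ensemble()` plants exact two-state χ₁ statistics: wells at
  −60°/180° (gauche⁻/trans, two bins ~8 bins apart at the default
  binning) with 5° within-well noise, coupled pairs drawn from a user 2×2
  joint table. Ground truth is attached to the object, and noiseless
  settings are exactly recovered by the analysis — that is the design
  contract, tested property-style.
* `make_jitter_ensemble()` adds independent per-coordinate Gaussian noise
  (per-residue SD), giving the analytic expectation RMSF = σ√3 used for
  parameter-recovery tests.
* `make_pose_groups()` generates pure-translation pose clusters, for which
  tethered RMSD equals translation distance exactly — a clean planted
  partition for the clustering stage.

What passing these tests shows: the estimators, filters and geometry are
correct against analytic and brute-force oracles under known statistical
structure. What it does not show: that real MD ensembles satisfy the
stationarity, frame-independence and two-state assumptions the generators
encode — autocorrelated frames inflate plugin MI, and real interfaces
involve packing and solvation physics the energy proxy deliberately
omits.

## Problem sizes and numerical choices

The test suite and examples run at desk scale by choice: ensembles of
300–500 frames, domains of 5–15 residues, 120–2,000 sampled poses for
pipeline checks and 10,000 for sampler-faithfulness statistics, 300 poses
for the planted-partition clustering check, SASA at 240 points where only
ranking (not absolute area) matters and 960 elsewhere. Bisection
tolerances (10⁻³ Å on the contact gap), the 10⁻⁸ orthonormality bound on
rotations, and the 10⁻⁸ Å degeneracy guard in clustering are all far below
any physically meaningful scale. Every stochastic entry point takes an
explicit seed and is covered by a byte-identical-rerun test.

## Known limitations

No side-chain repacking or refinement; no solvation/entropy terms; the
MI estimator does not correct for torsion autocorrelation time; ensembles
must share exact topology (no alignment across variants); mmCIF and
binary trajectory formats are out of scope. The pipeline ranks candidate
poses of one tethered system — it does not provide absolute binding
affinities or cross-system comparisons.
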