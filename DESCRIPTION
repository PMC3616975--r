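Package: tetherdock
Title: Informatics-Guided Tethered Protein-Protein Docking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for modelling two-domain protein complexes joined by a
    covalent linker. Nominates candidate interface sites from correlated
    torsional motions (corrected mutual information over backbone and
    side-chain dihedral distributions of a conformational ensemble), samples
    rigid-body poses of the mobile domain with a Gaussian perturbation
    scheme, filters poses by the geometric reach of the inter-domain linker,
    clusters surviving poses by tethered RMSD with an NMRCLUST-style penalty,
    and ranks representative poses with an interface metric panel: buried
    surface area, hydrophobic and ionic contacts, salt bridges, aromatic
    stacking, ensemble RMSF, and a pairwise nonbonded interaction energy.
    Includes deterministic synthetic-structure generators (ideal-geometry
    helical domains, planted-feature complexes, jittered and coupled-rotamer
    ensembles) so the full pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
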