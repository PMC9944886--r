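Package: ligshape
Title: Gaussian Shape Overlap, Ligand Matching and Affinity Curation for
    Protein-Ligand Complex Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for 3D ligand polypharmacology analysis over curated
    protein-ligand complex collections. Molecular volume is modelled as a
    sum of atom-centred isotropic Gaussians with closed-form self- and
    cross-overlap integrals, giving an exact shape Tanimoto coefficient.
    Rigid-body superposition maximises overlap volume from centre-of-mass,
    random-placement and principal-axes starting poses, and a
    conformer-ensemble protocol reports the best Tanimoto per ligand pair
    with all-vs-all matching above a reporting threshold. The package also
    implements database curation rules: resolution and model-quality
    filters, ligand validity classes, covalency detection, binding-affinity
    normalisation with the Kd > Ki > IC50 preference, affinity binning,
    cross-database discrepancy classification, and sequence-identity
    protein families with leader selection. Deterministic synthetic-data
    generators make every component testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
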