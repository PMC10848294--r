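Package: adsurf
Title: Protein Adsorption Analysis at Liquid/Vapor Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing of protein structures and trajectories for
    adsorption at planar water/vapor interfaces. Computes solvent-accessible
    surface area (SASA) from an explicit accessible-surface point cloud, the
    vapor-protruding area A_ads of an adsorbed protein, per-residue SASA
    differences between conformations, the spatial aggregation propensity
    (SAP) index and score, residue-level adsorption scores, mining of
    contiguous adsorbing sequences with hydrophobicity correlations, slab
    interface location from solvent density profiles, and standard
    conformational metrics (radius of gyration, superposed and per-domain
    RMSD). Includes seeded synthetic-data generators with analytic or
    high-resolution numeric ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    zoo,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
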