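Package: memscreen
Title: Membrane-Aware Structure-Based Virtual Screening and Hit Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for structure-based discovery of anionic
    GPCR ligands. Builds membrane-aware physics scoring grids (a two-level
    dielectric map from receptor and lipid coordinates, a finite-difference
    Poisson electrostatic potential, AMBER-style van der Waals lattices and a
    ligand-desolvation occlusion grid), docks rigid ligand conformers by
    matching-sphere triplet superposition, and triages ranked screens through
    fingerprint clustering, novelty filtering against known ligands,
    torsion-strain thresholds and required-interaction checks. Companion
    modules construct anion libraries by carboxylate/bioisostere substructure
    harvesting and building-block analog enumeration, benchmark enrichment
    with property-matched decoys and adjusted logAUC, and carry out the
    downstream pharmacology arithmetic: four-parameter logistic dose-response
    fits, Cheng-Prusoff conversion, Schild regression, ligand efficiency and
    noncompartmental pharmacokinetics with below-quantification censoring.
    Seeded generators produce every fixture the pipeline consumes, from toy
    membrane-embedded receptors to one-compartment concentration-time
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite,
    bio3d,
    minpack.lm,
    ChemmineR,
    ChemmineOB
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
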