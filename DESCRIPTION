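Package: abtriage
Title: Experimentally Guided Antibody-Antigen Pose Triage and In Silico
    Affinity Maturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for experimentally guided refinement of antibody-antigen
    docking models and rational affinity maturation. Provides a light-weight
    structure data model with PDB input/output, rigid transforms and
    least-squares superposition; Shrake-Rupley solvent-accessible surface
    area and buried-surface calculation; explicit intermolecular interaction
    detection (hydrogen bonds, salt bridges, pi-cation, pi-pi, hydrophobic
    contacts); a transparent residue-contact interaction energy with
    computational alanine scanning, species-switch checks and saturation
    mutagenesis in two side-chain accommodation modes; seeded rigid-body
    pose sampling with greedy RMSD clustering and receptor-blockade
    filtering against a surrogate receptor-ligand complex; consistency
    filtering of poses against experimental mutant phenotypes with
    partial-knockout ranking and validation-panel design; and
    affinity-maturation candidate filtering, dual-mode consensus, pooling
    with deduplication and diversity-constrained panel selection. A seeded
    synthetic-fixture generator builds toy multi-chain complexes with
    planted interfacial interactions at specified geometries so the whole
    pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
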