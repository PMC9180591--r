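Package: pepsmd
Title: Steered Molecular Dynamics Toolkit for Peptide-Membrane Pulling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for constant-velocity steered molecular
    dynamics of peptides pulled through a phospholipid bilayer. Builds
    simulation systems from amino-acid sequences by affine replication of a
    lipid template into an 8 x 8 x 2 bilayer, integrates classical equations
    of motion with a collisional thermostat and harmonic spring steering
    (terminal-atom and center-of-mass modes), records spring and membrane
    reaction force traces, and summarises them into peptide x velocity x mode
    tables of force maxima. Also computes sequence-derived physicochemical
    descriptors (molecular weight, net charge, isoelectric point,
    hydrophobicity, hydrophobic moment, aliphatic index, instability index)
    and correlates them with the force maxima.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
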