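Package: memsurf
Title: Protein-Membrane Surface Binding, Secondary Structure and Leaflet
    Asymmetry Analysis for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for protein-lipid bilayer molecular dynamics
    trajectories. Provides S4 containers for molecular structures and
    trajectories with PDB and GRO readers and writers, construction of
    peptide dimers from sequence, protein-membrane minimum-distance binding
    kinetics with attachment-time detection by a two-line changepoint fit,
    membrane-orientation angle tracking, a nine-state secondary-structure
    assigner based on backbone hydrogen-bond patterns with reduction to
    hydrogen-bonded classes, residue-contact minimum-distance maps with a
    ten-zone domain directory and replicate averaging, annular/non-annular
    lipid and water sorting around a membrane-bound protein, and leaflet
    lipid-number and area-per-lipid mismatch metrics for asymmetric
    bilayers. Includes seeded synthetic-fixture generators (pseudo-lipid
    bilayers, surface-binding trajectories, ideal helix and beta-sheet
    geometries) with analytically known ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
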