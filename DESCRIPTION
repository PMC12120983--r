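Package: confsel
Title: Conformer Ensemble Pruning, Clustering and Selection for
    Transition-Metal Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated selection of representative conformers from
    low-level (tight-binding) conformer ensembles of transition-metal
    complexes, ahead of expensive DFT refinement. Reads multi-structure
    XYZ ensembles with per-conformer energies and MDL Molfile
    connectivity, removes chirality-flipped structures, computes steric
    descriptors (percent buried volume, exact ligand cone angle, bite
    angle) and heavy-atom Kabsch RMSD, and selects conformer subsets by
    energy pruning, greedy RMSD pruning, descriptor extremes, PCA
    projection, or DBSCAN clustering on relative energy and RMSD.
    Predicted subsets are scored against DFT-minimum ground truth with a
    confusion-matrix framework, including epsilon sweeps for the
    clustering radius. A seeded generator of basin-structured synthetic
    ensembles with known ground truth supports end-to-end testing
    without quantum-chemistry calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    ChemmineR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
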