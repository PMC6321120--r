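Package: habitkit
Title: Crystal Habit Prediction and Supramolecular Geometry for Small-Molecule Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for solid-state analysis of small-molecule crystal
    structures. Reads crystal structures from CIF files, expands space-group
    symmetry, and partitions unit-cell contents into molecular units. Predicts
    the growth morphology of a crystal from per-face attachment energies
    (growth rate proportional to attachment energy) or from interplanar
    spacings (BFDH), via exact half-space intersection to a closed convex
    habit polyhedron with per-form facet-area shares. Computes the
    supramolecular geometry suite used in structure reports: hydrogen-bond
    tables with symmetry codes, ring perception with centroids, pi-stacking
    and T-shaped classification with slippage, Cremer-Pople ring puckering,
    Kitaigorodskii-style packing coefficients with grid-based void search,
    and Kabsch superposition RMSD. Includes deterministic synthetic-structure
    generators with known ground truth for validating every stage.
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
    igraph,
    rlang,
    tibble
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
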