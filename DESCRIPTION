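Package: permeakit
Title: Coarse-Grained Channel Permeation Simulation and Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how a small charged ligand passes through a
    pentameric mechanosensitive channel pore. Builds an idealized five-fold
    symmetric two-helix-per-subunit channel with a cytoplasmic lysine ring, a
    rigid polycationic ligand surrogate, ion baths and a membrane slab; runs
    coarse-grained Langevin dynamics with an external-electric-field force
    applied to a selected atom subset; and computes the permeation statistics
    used to characterize such events: the ligand-to-lysine-ring Z-coordinate
    difference, hysteresis crossing detection, stage segmentation, ion
    displacement, lipid contact numbers, two-selection RMSD, axis-angle helix
    rotation, pore-radius profiles with bottleneck detection, and an
    implicit-membrane finite-difference Poisson solvation energy combined with
    the molecular-mechanics energy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
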