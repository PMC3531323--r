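Package: esimap
Title: Electrostatic Hot-Spot Mapping via Perturbed Poisson-Boltzmann Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Locates electrostatic hot-spots on protein surfaces by computing
    families of linearized Poisson-Boltzmann potentials for perturbed
    structures (computational alanine-scan charge neutralizations,
    conformational ensembles, homologue families) and reducing them to
    per-grid-point electrostatic similarity index (ESI) maps against a parent
    structure. Includes pH-based formal-charge assignment and PQR export,
    a finite-difference linearized Poisson-Boltzmann solver with a
    solvent-excluded dielectric boundary, OpenDX grid input/output, surface
    projection of grid fields onto residues, and charge-position similarity
    clustering of multiple sequence alignments restricted to
    coordinate-defined functional faces, together with synthetic fixture
    generators so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    ape,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
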