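Package: pocketgrid
Title: Dual-Probe Grid Detection and Steered Segmentation of Protein Cavities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Geometry-based detection and spatial characterization of protein
    cavities on a regular 3D grid using mathematical morphology with two
    spherical probes: a small water-sized probe that delineates the interior
    of cavities and a large probe whose restricted access defines the cavity
    ceiling. Cavity points are the grid points reachable by the small probe
    but not by the large one; connected components are labeled with
    26-neighborhood connectivity and characterized by voxel volume, surface
    area, center of mass and lining residues. Supports user-steered search
    space segmentation (whole protein, box, or ligand-adjacent zones), a
    volume-ranked top-k benchmark protocol with a center-of-mass distance
    criterion, and generators for synthetic PDB fixtures with analytically
    known cavity geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
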