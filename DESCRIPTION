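Package: globulomeR
Title: Building and Analysing Annular Amyloid-Beta Globulomer Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Constructs polymorphic 12-peptide amyloid-beta (17-42)
    globulomer models from hairpin monomer or stacked-dimer building
    blocks by annular replication and a self-rotation scan, screens the
    candidates with a coarse physics-based score, and quantifies assembly
    structure and dynamics: RMSD/Rg free-energy landscapes, per-residue
    fluctuations, convex-hull sphericity, solvent-accessible surface
    area, sidechain contact and hydrogen-bond maps, salt bridges,
    reference-based dimer detection, PCA clustering of dimer
    configurations, and Boltzmann/Metropolis ensemble populations.
    Includes a synthetic-data generator (idealized hairpin templates and
    perturbed trajectories) so the full pipeline runs without molecular
    dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
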