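Package: hingescan
Title: Hinge-Bending Conformational Search for Ligand-Binding Domain Motions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates candidate ligand-bound (holo) conformations of a
    two-domain hinge-bending protein starting from its unbound (apo)
    structure. The mobile domain is swept through Euler rotations about the
    hinge on a 15-degree angular cell grid; each rotated structure is
    relaxed by bounded steepest descent, re-docked with a rigid-ligand
    surrogate docker, and scored by a fitness function combining docked
    energy, a stability score, and the squared radius of gyration. Fitness
    weights are trained by least squares against the static RMSD (sRMSD)
    figure of merit with leave-one-protein-out cross-validation, and the
    fitness is minimized by a per-axis line search over the angular grid.
    Includes a synthetic two-domain dumbbell generator so the full pipeline
    is testable without external structure downloads.
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
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
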