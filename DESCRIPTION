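Package: flexsas
Title: Ensemble Modelling of Flexible Multidomain Proteins Against Solution Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the solution structure of flexible multidomain
    proteins (antibodies in particular) against small-angle X-ray and neutron
    scattering data. Generates stereochemically acceptable conformers by
    torsion-angle Monte Carlo sampling of hinge peptides with rigid subunits,
    computes theoretical scattering curves by the Debye equation (weighted
    pair-distance histogram) or a golden-ratio spherical quadrature, scores
    conformers against experimental curves with a crystallography-style
    R-factor, selects and clusters best-fit ensembles by principal component
    analysis, and cross-validates with Guinier, cross-sectional Guinier,
    distance-distribution P(r), normalized Kratky, and convex-hull
    sedimentation-coefficient analytics. Includes a synthetic-data generator
    for antibody-like mock models and simulated noisy experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    bio3d,
    pracma,
    withr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
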