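Package: ppigrid
Title: Partner-Specific Protein-Protein Interface Prediction from Reduced
    Surface Property Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts partner-specific protein-protein interaction interfaces
    by reducing each protein's solvent-accessible surface to six 2D grids of
    mapped physicochemical properties (atomic charge, Wimley-White
    hydrophobicity, evolutionary conservation) and locating the maximally
    complementary placement of the two partners' grids by full 2D
    cross-correlation over face pairs, in-plane rotations and translations.
    Includes residue-depth surface selection from a Shrake-Rupley accessible
    surface point cloud, biased k-means face segmentation, a consistency rule
    over the top-scoring placements, permutation (shuffle) significance
    testing of the top score, and confusion-matrix evaluation against bound
    complexes. Ships a synthetic-fixture generator with engineered
    complementary-charge patches and smooth structural distortion so the full
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
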