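Package: cardiomapr
Title: Structure-Function Mapping of Intact Hearts from Optical and
    Cleared-Tissue Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for aligning panoramic optical voltage maps of intact
    hearts with cleared-tissue structural imaging and quantifying their
    relationship. Processes voltage movies into activation, APD80 and
    delta-APD maps; derives conduction-velocity vector fields, tissue
    activation curves and activation times; estimates axial myofiber
    orientation fields from autofluorescence and computes a regional
    anisotropy index; traces tubular sympathetic nerve fibers, filters
    spurious junctions, and computes size-binned length and prevalence
    indices; registers structural to optical frames via fiducial-based
    homography; and provides axial circular statistics, a Mantel matrix
    permutation test, and exact small-sample rank tests. A seeded
    synthetic-heart generator (anisotropic eikonal activation, parametric
    optical action potentials, warped vessel trees, rendered nerve tubes)
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
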