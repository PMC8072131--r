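Package: nichemorph
Title: 3D Morphometry of the Ventricular-Subventricular Zone Stem Cell Niche
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the vascular and progenitor architecture of the
    ventricular-subventricular zone (V-SVZ) neurogenic niche from
    multi-channel 3D image stacks: vessel skeletonization with per-branch
    tortuosity and distance-transform diameters, vessel and neuroblast-chain
    volume densities, chain eccentricity from 3D principal components,
    marker colocalization with apical filtering of stem cells, minimum
    distances from cells and chain surfaces to the vessel surface,
    time-lapse population-growth slopes, and the associated group-comparison
    statistics (rank-sum, Kolmogorov-Smirnov, two-way ANOVA with Sidak or
    Tukey post hoc tests). A synthetic phantom generator with analytic
    ground truth makes every estimator testable without imaging data.
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
    jsonlite,
    generics,
    tiff,
    readr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
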