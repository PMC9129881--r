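Package: tundraline
Title: Individual-Based Simulation of Siberian Treeline Migration and
    Tundra Area Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how fast the latitudinal treeline of the Siberian
    tundra-taiga ecotone tracks climate warming. The package builds
    millennium-scale monthly climate and wind forcing for latitudinal
    transects (proxy-extended, scenario-appended, regionally adjusted),
    runs an individual-based larch life-cycle simulator (growth, wind-driven
    ballistic seed dispersal, production, establishment, mortality) on
    wrapped two-dimensional transects, extracts single-tree, treeline and
    forestline positions together with a climate-analogue (isotherm
    tracking) baseline, quantifies migration lag and overshoot, and converts
    treeline advances into tundra-area time series on equal-area corridor
    geometries. All user-facing functions take and return tidy data frames.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
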