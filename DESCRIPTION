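Package: candycode
Title: Encoding, Matching and Simulation of Colored-Particle Pill Identifiers
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for edible physical unclonable functions made from random
    multicolored particles (nonpareils) scattered on a pill surface. Converts a
    particle pattern into a canonical multiset of Delaunay-neighborhood color
    strings, stores known-good string sets in an inverted-index database and
    matches suspect patterns to issue authenticity verdicts, simulates particle
    placement by random sequential adsorption, renders and detects synthetic
    pill photographs, and quantifies library uniqueness via shared-string
    statistics, log-linear scaling fits and extrapolation to very large
    libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils,
    grDevices,
    png,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    deldir,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
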