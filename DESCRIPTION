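Package: songscape
Title: Landscape Connectivity and Birdsong Repertoire Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for linking between-population dissimilarity of learned
    birdsong repertoires to landscape connectivity. Builds per-species
    conductance surfaces from expert-elicited land-cover permeability
    coefficients corrected for elevation-dependent avian-malaria mortality,
    computes pairwise effective resistance between focal landscapes with a
    circuit-theory (graph Laplacian) solver, derives Sorensen repertoire
    beta-diversity from syllable presence tables, compares repertoires with
    permutation-based multivariate tests and ordination, and regresses
    beta-diversity on resistance and geographic distance (isolation by
    resistance vs. isolation by distance), including min/mean/max coefficient
    sensitivity variants. A seeded synthetic-scenario generator produces
    complete test landscapes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
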