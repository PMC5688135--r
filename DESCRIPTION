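Package: forestpat
Title: Spatial Point Patterns and Habitat Association in Mapped Forest Plots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for stem-mapped forest census plots: per-species
    pair-correlation functions with Ripley isotropic edge correction and
    Monte-Carlo simulation envelopes under complete spatial randomness and
    heterogeneous (inhomogeneous) Poisson null models; topographic variables
    (elevation, slope, aspect, convexity) derived from a corner-elevation grid;
    habitat classification of 20-m cells by a multivariate regression tree;
    torus-translation tests of species-habitat association; canonical
    correspondence analysis of community composition against topography with
    permutation tests; and a seeded synthetic forest generator (rugged terrain,
    log-series abundances, Thomas-process clustering, habitat-biased thinning)
    with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vegan,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
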