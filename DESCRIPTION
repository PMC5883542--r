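Package: figcodiv
Title: Barcode Delimitation and Codivergence Testing for Fig Wasp
    Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Community-level molecular analysis of chalcid fig wasp
    assemblages sampled from a shared host fig in two biogeographic
    regions. Provides Kimura two-parameter barcode distances with
    pairwise deletion and saturation flagging, MOTU clustering across a
    cutoff sweep with barcoding-gap detection, two-marker (COI + ITS2)
    species delimitation by congruent monophyly and distance thresholds,
    identification of intercontinental sister-species pairs, a
    hierarchical approximate Bayesian computation (hABC) test of
    synchronous versus guild-staggered divergence built on a
    two-population isolation coalescent, Bayes-factor model comparison on
    Raftery's scale, strict-molecular-clock split dating with site
    bootstrap intervals, genus-by-guild community composition tables, and
    a coalescent community simulator with known truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
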