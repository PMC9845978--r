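Package: phylosyndrome
Title: Phylogenetic Trait-Syndrome Association Analysis for Binary Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing macroevolutionary associations among binary
    organismal traits on a phylogeny, motivated by comparative studies of
    larval protective coloration and host-plant ecology. Provides binary
    trait coding with two-colour composite expansion and rarity filtering,
    phylogenetic logistic regression with a Firth-type penalty and an
    estimated phylogenetic signal parameter, Benjamini-Hochberg false
    discovery rate control within a-priori and exploratory hypothesis
    families, an observer-bootstrap consensus rule for supported
    associations, and a synthetic-data generator (birth-death trees,
    phylogenetically structured binary traits, two-observer scoring noise)
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
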