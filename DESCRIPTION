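Package: hybridhic
Title: Homolog Proximity Analysis for Hi-C of Hybrid Diploid Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies homolog proximity from Hi-C contact maps of hybrid
    diploid budding yeast, in which reads are assignable to the two parental
    chromosome sets. Provides hybrid-genome bin indexing with centromeric
    distance annotations, ligation-pair filtering, binning and single-pass
    marginal normalization of contact matrices, a volume-exclusion bead-chain
    polymer model of the Rabl-like orientation as a homology-agnostic null,
    a homolog-proximity statistic with centromeric-distance and arm-length
    controls and bootstrap uncertainty, condition-comparison statistics
    (differential maps and centromere-distance-stratified rank-sum tests),
    and a seeded synthetic Hi-C generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
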