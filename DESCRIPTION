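Package: wgdfrac
Title: Fractionation Statistics and Genome-Collapse Simulation After
    Whole-Genome Duplication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the collapse of gene complement following
    whole-genome duplication (WGD) at gene-order resolution.  Builds
    analytical units (pairs of homeologous single-copy segments bounded by
    orientation-consistent duplicate pairs) from gene orders and
    WGD-paralog maps, fits a geometric model to the distribution of
    single-copy run lengths by minimum chi-square, measures fractionation
    bias with folded-binomial concentration statistics against a simulated
    null, and provides the post-WGD collapse simulator (paralog-pair
    reduction with geometric deletion runs, inversions and reciprocal
    translocations) used for that null.  Also includes score-bracket and
    best-reciprocal-hit filters for assigning WGD paralog pairs from
    all-against-all protein hit tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
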