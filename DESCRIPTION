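Package: geoimpute
Title: Demographically Weighted Geoimputation and Positional Error Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for geoimputation: assigning a fine-resolution coordinate
    to a person-level record known only at a coarse census unit (block group,
    tract, or county), using block-level demographic counts as ancillary data.
    Implements four strategies -- a uniform random point in the coarse unit, a
    random point restricted to demographically matching blocks, the centroid
    of the maximum-weight block, and the demographically weighted mean of
    block centroids -- together with a full evaluation framework: controlled
    coarsening of records with known coordinates, planar error distances,
    stratified summaries by race, sex, age group and population density,
    multiple-imputation validation of the stochastic strategies, sensitivity
    analysis across spatial-unit levels, tract-level accuracy aggregation and
    inverse-distance-weighted error surfaces. A synthetic census-like
    geography and microdata generator makes every pipeline stage testable
    without restricted-access registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
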