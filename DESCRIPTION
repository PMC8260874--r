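Package: conservatome
Title: Cross-Species Conservation Analysis of Time-Course Biofluid Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for two-species (human/pig) time-course
    targeted-proteomics studies of cerebrospinal fluid and serum. Provides a
    synthetic-data generator with planted ground truth, the standard
    preprocessing chain for targeted-MS abundance matrices (log transform,
    batch residualization, detection filtering, half-minimum imputation,
    within-species z-normalization), moderated linear-model differential
    abundance with empirical-Bayes variance shrinkage, sample-network
    modularity curves, k-means consensus clustering of temporal trajectories
    with CDF-area model selection, and a cross-species conservation suite:
    neighborhood analysis of conserved coexpression (NACC), rank-rank
    hypergeometric overlap (RRHO) with permutation nulls, pi1 estimation,
    and dynamic-time-warping alignment of proteome time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
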