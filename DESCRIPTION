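Package: bpmcut
Title: Between-Pathway Modules from Genetic Interaction Data via
    Randomized Local Max-Cut
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers generalized Between-Pathway Modules (BPMs) --
    pairs of gene sets with predominantly negative epistasis between the
    sets and positive epistasis within them -- from high-throughput
    genetic-interaction screens (E-MAP, SGA, dSLAM). An ensemble of
    random graph bipartitions is driven to local max-cut optima by
    single-vertex moves; per-gene co-occurrence frequencies across the
    ensemble yield one candidate module pair per gene, which are then
    pruned by module size and pairwise Jaccard overlap. Includes an
    offline GO-enrichment stage (hypergeometric tests with
    resampling-based multiple-testing correction), a synthetic generator
    of interaction tables with planted module structure for end-to-end
    validation, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    optparse,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
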