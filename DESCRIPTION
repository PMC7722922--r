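Package: noveltag
Title: Behavioral-Tagging Analysis of Novelty Effects on Memory Consolidation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for studies of behavioral tagging in
    virtual environments: free-recall retention scores from STM/LTM hit
    counts, exploration metrics (unique 2x2-block tiles and group occupancy
    difference maps) from 100 ms avatar position logs, Bayesian linear
    models of retention with weakly informative Student-t priors sampled by
    a built-in adaptive Metropolis-within-Gibbs sampler, HDI + ROPE
    equivalence decisions on group contrasts and per-group covariate slopes,
    two-way factorial ANOVAs with partial eta squared for control variables,
    and a synthetic cohort/trajectory generator for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
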