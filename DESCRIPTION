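Package: elevbreak
Title: Breakpoint Analysis of Biodiversity and Ecosystem Multifunctionality
    Along Elevational Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and tests abrupt elevational transitions (breakpoints) in
    plant and soil-bacterial communities and in ecosystem functions sampled
    along mountain gradients, and attributes variation in diversity and
    multifunctionality to contemporary versus geological predictor blocks.
    Provides continuous two-segment (broken-stick) regression with bootstrap
    confidence intervals and a permutation test of the slope change,
    compositional turnover profiling between adjacent elevations (Bray-Curtis
    dissimilarity with PERMANOVA pseudo-F), regression-tree split-density
    profiling, detrended correspondence analysis, cross-mountain similarity
    comparisons, averaging-based ecosystem multifunctionality with
    subset-robustness curves, multidiversity, geochemical weathering indices,
    AICc model averaging, geological-increment regressions, variation
    partitioning, and recursive path analysis with effect decomposition.
    A seeded synthetic-gradient generator with a planted fault provides ground
    truth for every stage, and a pipeline runner reproduces the full analysis
    on a dataset directory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
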