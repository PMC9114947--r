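Package: epiclover
Title: Genetic and Epigenetic Variation Analysis for Dominant Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of genetic (AFLP) and epigenetic (MSAP) variation in
    hierarchically structured plant populations scored as dominant
    presence/absence markers. Implements 'mixed scoring 2' transformation of
    paired HpaII/MspI MSAP profiles into u/m/h subepilocus matrices,
    band-based diversity statistics (Shannon information index, polymorphism
    and private-band percentages), two-level hierarchical analysis of
    molecular variance (AMOVA) with Phi-statistics and permutation tests on
    squared Euclidean distances, pairwise population PhiPT matrices,
    isolation-by-distance and isolation-by-habitat matrix tests (simple and
    partial Mantel, multiple matrix regression with randomization), mean
    weighted Ellenberg indicator values from vegetation releves, group
    comparison statistics, and a synthetic fragment-data generator with known
    ground truth for the full analysis chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'methods-classes.R'
    'io.R'
    'scoring.R'
    'diversity.R'
    'amova.R'
    'matrixTests.R'
    'eiv.R'
    'groupStats.R'
    'simulate.R'
    'referenceData.R'
    'pipeline.R'
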