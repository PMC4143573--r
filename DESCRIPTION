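Package: ThermoScreen
Title: Cross-Strain Expression Screening for Thermotolerance Genes in Yeast
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies genes whose heat-induced expression tracks strain-level
    thermotolerance in Saccharomyces cerevisiae. Provides doubling-time
    estimation from OD600 growth curves, a three-stage cross-strain fold-change
    screen on expression matrices (percentile-shift normalisation, low-intensity
    and detection-flag filters, t-test differential filter, rank-concordance
    selection), qPCR relative quantification via external standard curves with
    reference-gene normalisation, and regression of expression ratios on
    doubling-time ratios. Includes a synthetic-data generator with a planted
    thermotolerance-correlated gene for ground-truth benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: GeneExpression, Microarray, qPCR, Transcriptomics
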