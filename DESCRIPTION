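Package: methcross
Title: Direction-Aware Differential DNA Methylation Analysis with
    Threshold-Crossing Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-CpG differential methylation analysis for Illumina 450K-style
    beta-value matrices with empirical-Bayes variance moderation, followed by
    direction-aware classification of significant CpGs by group-mean beta state
    relative to the 0.5 boundary (low-to-high and high-to-low threshold
    crossings), top-gene ranking by aggregated log fold change, stratified
    cross-tabulation over CpG-island relation and gene-structure categories,
    and hypergeometric over-representation analysis over GMT gene sets.
    Includes a synthetic-data generator that emulates bimodal 450K beta
    distributions with planted threshold-crossing effects, multi-dataset
    structure, probe-level missingness and many-to-many probe-gene mappings,
    plus volcano, heatmap, dendrogram and PCA visualisations and a staged
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    grid,
    tools,
    yaml,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
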