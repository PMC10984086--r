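Package: gcniche
Title: Spatial and Chromatin Profiling of Germinal Center Dark and Light Zones
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of germinal-center dark-zone (DZ) and
    light-zone (LZ) compartmentalization. Provides synthetic generators for
    germinal-center cell maps, nuclear-stain images and expression designs
    with planted ground truth; nuclear segmentation and chrometric (chromatin
    and morphology) feature extraction including the heterochromatin-to-
    euchromatin ratio; a random-forest DZ/LZ nucleus classifier with
    stratified cross-validation and a no-information-rate signed-rank test;
    nearest-neighbour randomization tests for cell segregation and
    aggregation, DZ/LZ interface delineation with signed-distance bands and
    density profiles; permutation and bootstrap correlation inference;
    paired moderated-t differential expression, signature scoring, tertile
    stratification, running-sum enrichment and cross-cohort gene/T-cell
    correlation analysis; plus file I/O and a reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Rcpp,
    EBImage,
    randomForest,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
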