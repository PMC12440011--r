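Package: organoidquant
Title: Quantification of Epithelial Detachment Phenotypes in Kidney Organoid Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the epithelial-detachment phenotype of human kidney
    organoids from multi-channel fluorescence images: set-level background
    estimation, z-projection, global thresholding, partition of each nephron
    marker channel (PODXL, ECAD, LTL) into intact versus detached area,
    live/dead area ratios, whole-well organoid census by three-marker
    coincidence, and position-based time-lapse tracking of detachment. Ships
    the accompanying statistical layer (one-way ANOVA with Fisher's LSD,
    fold changes, SEM summaries, 2^-ddCt relative qPCR quantification) and
    the transcriptomic filter and overlap arithmetic (cell-level QC rules,
    differential-expression thresholding, cross-dataset directionality
    concordance). A synthetic-data module generates images, time-lapse
    series, count matrices and paired DE tables with exact ground truth, so
    every stage is testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
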