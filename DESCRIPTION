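Package: arcnet
Title: Immediate-Early-Gene Expression and Functional Connectivity
    Refinement in Neuronal Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking Arc/c-Fos immediate-early-gene
    expression in individual cultured neurons to changes in correlated
    firing after chemically induced long-term potentiation. Covers
    nuclear ROI segmentation and two-normal mixture thresholding of
    marker intensities, calcium trace extraction with silent-cell
    background/photobleach correction, fast-oopsi-style MAP spike
    deconvolution, spike time tiling coefficient (STTC) adjacency
    matrices, Intrinsic Connectivity Distribution (ICD)
    stretched-exponential refinement metrics, correlation-change
    classification, distance analyses, and stepwise linear regression of
    Arc-positive percentages. Ships a ground-truthed synthetic-culture
    generator (network-burst spike trains, AR(1) calcium fluorescence,
    renderable nuclear/marker images, bimodal marker intensities) so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
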