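Package: divscape
Title: Landscape Genetics of Microsatellite Diversity and Ensemble Habitat
    Suitability Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landscape-genetic analysis of codominant microsatellite
    (SSR) data in fragmented tropical tree populations: multilocus diversity
    and inbreeding statistics (allelic richness, Shannon index, expected and
    observed heterozygosity, F_IS with permutation tests), Nei pairwise and
    global F_ST, two-level AMOVA, bootstrap-corrected circular-neighborhood
    diversity rasters including locally-common-allele richness, an EM maximizer
    of the admixture ancestry likelihood with Evanno delta-K model selection,
    and an ensemble habitat-suitability framework built around calibrated AUC
    evaluation against a geographic null model, Mann-Whitney model retention,
    exhaustive anchored ensemble search, max-sensitivity-plus-specificity
    thresholding and multi-scenario consensus maps. Includes seeded generators
    for Balding-Nichols genotype data and autocorrelated environmental
    landscapes so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    mgcv,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
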