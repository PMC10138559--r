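Package: toxmod
Title: Gene-Set Activation Scoring for Toxicogenomic Injury Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for toxicogenomic expression studies: per-gene
    log2 fold changes and Welch-test differential expression with
    Benjamini-Hochberg FDR control, aggregate fold-change scoring of gene-set
    injury modules (magnitude AAFC and directional AFC statistics) against a
    Monte-Carlo permutation null with z-score activation calls, directional
    pathway scoring and hypergeometric over-representation analysis, and
    cross-condition comparisons (DEG overlap matrices, common-gene ranking,
    PCA embeddings, module-score correlations). Includes a seeded synthetic
    expression-data generator emulating a two-platform, two-dose, two-time
    toxicant exposure design with planted module effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
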