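Package: metaboqtl
Title: Metabolome Quantitative Genetics for Biparental RIL Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for metabolite quantitative trait locus (mQTL)
    analysis in recombinant inbred line (RIL) populations: trait descriptive
    genetics (coefficient of variation, broad-sense heritability from
    replicate-structured one-way ANOVA, correlation networks), inclusive
    composite interval mapping with stepwise cofactor selection, genome-wide
    permutation LOD thresholds and 1.5-LOD support intervals, replicate
    consolidation of mQTL, permutation-based mQTL hotspot calling,
    mQTL-pQTL colocalization, and metabolite-based prediction of agronomic
    traits by kernel BLUP and LASSO with cross-validated predictability.
    Includes a seeded synthetic RIL-population generator with known genetic
    architecture so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
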