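Package: qstfst
Title: Quantitative-Genetic Divergence Analysis for Half-Sib Common-Garden Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests for divergent selection on quantitative traits measured in
    open-pollinated half-sib progeny trials by comparing trait differentiation
    (QST) among genetic clusters with the genome-wide distribution of per-SNP
    Weir-Cockerham FST. Provides restricted-maximum-likelihood variance
    component estimation for the standard common-garden mixed models (block,
    family and cluster effects), narrow-sense heritability as a half-sib
    intraclass correlation, per-ring analyses of wood traits over cambial age,
    genotype quality-control filters and principal component analysis, and a
    synthetic-data generator (Balding-Nichols cluster divergence, half-sib
    family structure, randomized incomplete blocks) so that every stage of the
    analysis can be validated without access to the original field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    car,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
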