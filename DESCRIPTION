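Package: taxgate
Title: Compositional Ordinal Differential Abundance with Taxonomy-Gated
    Stepdown FDR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline relating gut-microbiome composition to an
    ordered clinical-severity spectrum. Provides compositional transforms
    (centered log-ratio, tree-based isometric log-ratio balances, Aitchison
    distance), Shannon alpha diversity with two-group and ordinal
    three-group tests, PERMANOVA on compositional distances, per-taxon
    rank-based ordinal and discrete differential-abundance tests with
    Benjamini-Hochberg adjustment, a taxonomy-gated stepdown (TSD)
    hierarchical testing procedure, HLA-by-taxon and antibody-titer-by-
    disease interaction models, and a seeded synthetic 16S cohort generator
    for end-to-end validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    MASS,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
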