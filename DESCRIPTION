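Package: mbassoc
Title: Two-Part Association Between Gut Microbiome Features and Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for association analysis between zero-inflated microbiome
    feature tables (OTU counts) and quantitative host traits using a two-part
    (hurdle) model: a presence/absence regression, an abundance-given-presence
    regression, and an unweighted Z-score (Stouffer) meta-combination, with the
    minimum component p-value as the final association statistic.  Includes
    OTU-table preprocessing (rarefaction, relative-abundance conversion,
    prevalence/abundance filtering, taxonomic aggregation), covariate
    adjustment of traits, alpha-diversity indices (observed species, chao1,
    ACE, Shannon, Simpson) with rank-sum group comparison, permutation-based
    false-discovery-rate control, cross-validated estimation of the trait
    variance explained by an additive microbiome risk score, and a synthetic
    cohort generator with planted presence and abundance effects for
    truth-known benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
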