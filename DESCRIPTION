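Package: eqtlcre
Title: Cis-eQTL Mapping and Integration with Cis-Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for cis-eQTL analysis across cell types:
    Bayes-factor association mapping with grid priors over additive and
    dominance effects, LD-block-aware tiered discovery of independently
    associated SNPs (allelic heterogeneity), permutation-based FDR,
    cross-study replication and cell-type-specificity calls, five-model
    bivariate Bayes factors for differential eQTLs, SNP versus
    cis-regulatory-element overlap statistics with logistic enrichment
    models, and random-forest prediction of eQTL cell-type specificity.
    Includes a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    mclust,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
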