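Package: opgblup
Title: Marker-Based Decomposition of Genetic Variance in Open-Pollinated Family Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree (A) and genomic (G) relationship kernels for
    open-pollinated progeny trials, multi-kernel average-information REML
    estimation of additive, dominance and epistatic variance components,
    narrow-sense heritability with delta-method standard errors, BLUP
    breeding values with prediction errors, AIC model comparison, an
    eigen-diagnostic of the sampling correlation of variance estimates,
    and restricted (random, block and family) cross-validation of
    prediction accuracy. Includes a synthetic open-pollinated family
    generator with hidden-relatedness contamination (selfs and full-sibs
    inside assumed half-sib families) for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
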