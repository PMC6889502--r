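Package: stemscreen
Title: Dual-Signature Connectivity Screening for Anti-Leukemia-Stem-Cell
    Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: In silico drug-repurposing screen for compounds predicted to
    extinguish a leukemic stem cell (LSC) transcriptional program while
    sparing the normal hematopoietic stem cell (HSC) program. Builds up/down
    probe tag-set signatures from differential-expression tables, scores them
    against a perturbation rank database with the Connectivity Map build-02
    Kolmogorov-Smirnov tag statistic, summarises compounds with seeded
    permutation p-values, and partitions the compound universe with a
    dual-signature selection rule. Downstream in vitro screen analytics
    include DMSO-relative viability normalisation, +/-50 percent hit calls,
    compound categorisation across flow-sorted leukemic populations,
    four-parameter logistic dose-response fits with LC50, and selectivity
    ratios. A seeded synthetic-data module generates rank matrices with
    planted signature-inverting compounds and screen tables governed by known
    dose-response curves, with ground-truth manifests for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
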