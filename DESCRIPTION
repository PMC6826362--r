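Package: hetexpress
Title: Heterosis Statistics and Inheritance-Mode Classification for
    Reciprocal-Cross Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of gene-expression inheritance in
    reciprocal crosses: mid-parent heterosis percentage and its t-test on
    individual-level phenotypes, FPKM filtering and negative-binomial Wald
    differential expression across purebred and hybrid contrasts
    (including an explicit mid-parent contrast), classification of genes
    into twelve inheritance-mode types collapsed to five categories
    (additivity, high-/low-parent dominance, over-/under-dominance),
    hypergeometric over-representation analysis of non-additive gene
    lists against GMT gene sets, and 2^-ddCt relative quantification of
    qPCR validation data. Ships a seeded negative-binomial simulator for
    reciprocal-cross count matrices with known ground-truth modes.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
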