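Package: dksig
Title: Dual Kolmogorov-Smirnov Gene Signature Discovery and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers class-specific up- and down-regulated gene signatures
    from a labelled expression matrix by tissue-set enrichment analysis, an
    inversion of gene set enrichment analysis in which samples of one class are
    tested for bias in each gene's expression-ordered sample list using a
    Kolmogorov-Smirnov running-sum statistic. New samples are classified by
    GSEA-style enrichment of the discovered signatures, with weighted and
    rescaled scoring variants, 0.632+ bootstrap error estimation and a
    signature-size sweep to select the number of genes per class. Includes a
    synthetic expression data generator, GMT and JSON model interchange, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
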