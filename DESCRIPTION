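Package: trivalent
Title: Trivalent Promoter Chromatin-State Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies promoter CpG islands by their H3K4me1, H3K4me3 and
    H3K27me3 chromatin signatures, calls H3K4me1 bimodal/unimodal pattern
    transitions between paired cell states (bimodal-loss and bimodal-gain
    groups accompanying H3K27me3 loss), scores tissue specificity of gene
    expression with the Tau index, and models the association between
    histone-mark changes at promoters and enhancers and tissue-specific
    expression with logistic regression. Ships a synthetic-data generator
    that plants all ground-truth structure (promoter classes, pattern
    transitions, tissue-specific genes, differential expression) so the
    whole pipeline can be exercised and validated end to end without
    external sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
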