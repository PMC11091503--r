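Package: hetcirc
Title: Tissue-Specific circRNA Expression and Heterosis for Feed
    Efficiency in Reciprocal-Cross Chicken
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking tissue-specific circular RNA
    (circRNA) expression to mid-parent heterosis for feed intake and feed
    efficiency in a reciprocal-cross layer chicken design (purebred WW and
    YY lines and their reciprocal crosses WY and YW).  Provides residual
    feed intake (RFI) phenotype modelling, a mid-parent heterosis test,
    CPM-based expression filtering with single-parent-expression calls and
    genomic region classification of circRNAs, negative-binomial
    differential tests with inheritance-pattern classification (additive,
    dominant and over-/under-dominant patterns I-XII), signed weighted
    co-expression module detection (topological overlap, eigengenes,
    module-trait correlation) and circRNA-mRNA candidate network
    construction.  A synthetic-data generator with fully known planted
    truth exercises every stage end to end.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    igraph,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
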