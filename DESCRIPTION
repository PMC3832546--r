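Package: spliceLRT
Title: Differential Isoform Expression and Splicing via Hierarchical
    Likelihood Ratio Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint estimation of transcript-isoform abundances from
    multi-condition RNA-Seq read counts under a linear Poisson model, and
    classification of each gene into one of three nested expression models
    (no differential expression; differential expression without
    differential splicing; differential splicing) with a two-round
    hierarchical likelihood ratio test. Includes EM fitting of all three
    models with Wald confidence intervals, ranking of differentially
    spliced genes by an L1-distance statistic, an exon-inclusion (psi)
    estimator from exon-exon junction read counts, and a Poisson
    simulation engine for studying type-I error and power of the test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    rtracklayer,
    Rsamtools,
    GenomicAlignments,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
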