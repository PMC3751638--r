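Package: acetylscan
Title: Integration of Promoter Histone-Acetylation ChIP-Seq with Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating histone-acetylation ChIP-seq binding at
    transcription start sites (TSSs) to gene expression across treatment
    groups. Provides TSS-centric tag quantification (tags-per-million
    normalization, nearest-promoter assignment, metagene profiles),
    sliding-window Poisson enrichment calling against an input control,
    fold-change/p-value differential expression with the signed fold-change
    convention, Z-score/100-gene-bin expression-versus-binding regression,
    multi-condition overlap partitions, and expression/binding concordance
    classification (increased, decreased, no-change, absent). A synthetic-data
    module generates annotations, expression matrices and tag libraries with
    known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
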