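Package: SialoKit
Title: Sialotranscriptome Annotation and Differential Expression for
    Salivary Gland RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for building and analysing the salivary
    gland transcriptome (sialome) of an arthropod from assembled
    transcripts: six-frame ORF scanning and coding-sequence extraction
    anchored either by protein homology coverage or by a heuristic
    signal-peptide call with most-5' methionine start selection, greedy
    identity-threshold consolidation of the coding set, TPM quantification
    with a per-condition presence filter, ordered keyword-vocabulary
    functional classification of homology hits into sialome classes and
    secreted-protein families, class and family abundance summaries, and a
    two-group negative-binomial exact-test differential expression module
    with common-dispersion estimation, BH false discovery rates and MDS
    sample ordination. A fully labelled synthetic-data generator emulating
    a virus-infected versus control salivary-gland study design makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    BiocGenerics,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Transcriptomics, RNASeq, DifferentialExpression, Annotation
RoxygenNote: 7.3.3
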