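Package: circSponge
Title: Consensus circRNA Identification and ceRNA Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers circRNA-associated competing-endogenous-RNA (ceRNA) networks
    from multi-layer RNA-seq count data. Provides consensus back-splice-junction
    calling across multiple circRNA caller outputs, CPM/FPKM/BSJ-CPM
    normalization, a quantile-adjusted exact negative-binomial two-group
    differential-expression test with Benjamini-Hochberg FDR control, canonical
    miRNA seed-site prediction (6mer, 7mer-A1, 7mer-m8, 8mer) on linear and
    circularized targets, direction-constrained circRNA-miRNA-mRNA triplet
    assembly with Pearson co-expression filtering, circRNA/host-gene correlation
    screening, RT-qPCR relative-quantification utilities, and a ground-truthed
    synthetic data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    rtracklayer,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Transcriptomics, DifferentialExpression, Normalization, Network
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cerna-network.R'
    'utils.R'
    'circ-consensus.R'
    'de-analysis.R'
    'io.R'
    'mre-prediction.R'
    'normalize.R'
    'pipeline.R'
    'qpcr.R'
    'sample-design.R'
    'simulate-callers.R'
    'simulate-counts.R'
    'simulate-sequences.R'
    'synthetic-truth.R'
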