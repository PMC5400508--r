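Package: chromdyn
Title: Chromatin Mark Dynamics Under Global Histone-Mark Depletion
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of ChIP-seq and RNA-seq dynamics when a
    histone mark is globally depleted, as after loss of a Polycomb (PRC2)
    subunit. Provides binned coverage and ChIP-minus-input signal tracks,
    depth and ChIP-DNA-factor normalization, background z-score
    standardization that is exactly invariant to global rescaling, a
    simplified broad-peak caller with Poisson enrichment tests, peak set
    Venn partitioning and genomic-feature annotation, nearest-TSS peak
    assignment, k-means classification of derepressed genes (C1-C3) and of
    co-occupied regions (E1-E3), a negative-binomial Wald test for
    differential expression, WT-quartile stratification, rescue-ratio
    binning, and an exact/approximate Wilcoxon-Mann-Whitney rank-sum test.
    A synthetic-data generator plants known gene classes, locus-specific
    mark effects and a global depletion factor so that every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    edgeR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: ChIPSeq, Epigenetics, Normalization, DifferentialExpression,
    Clustering, Coverage
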