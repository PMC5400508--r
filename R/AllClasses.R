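#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   strand mcols mcols<- findOverlaps countOverlaps reduce resize coverage
#' @importFrom IRanges IRanges Views viewSums overlapsAny subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits Rle runValue runLength
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels seqinfo
#' @importFrom stats kmeans p.adjust pnorm ppois rpois rnbinom rlnorm rnorm
#'   median quantile sd var cor lm coef setNames complete.cases
#' @importFrom utils read.table write.table combn head tail
NULL

setClassUnion("numeric_OR_NULL", c("numeric", "NULL"))

#' CoverageTrack: binned read counts for one sequencing library
#'
#' Fixed-width, non-overlapping bins tiled over a genome, holding
#' non-negative per-bin read counts (or rescaled counts after
#' normalization), together with the library's total aligned-read count.
#' Bin `i` on a chromosome covers the 0-based half-open interval
#' `[(i-1)*binWidth, i*binWidth)`.
#'
#' @slot bins named list of per-chromosome numeric vectors.
#' @slot binWidth bin width in bp.
#' @slot totalAligned total aligned reads in the library.
#' @slot genome a [GenomeInfoDb::Seqinfo] describing the genome.
#' @slot provenance list recording normalization steps applied.
#' @export
setClass("CoverageTrack",
    representation(bins = "list", binWidth = "integer",
                   totalAligned = "numeric", genome = "Seqinfo",
                   provenance = "list"),
    prototype(provenance = list()))

setValidity("CoverageTrack", function(object) {
    sl <- seqlengths(object@genome)
    if (!identical(names(object@bins), names(sl)))
        return("bin list names must equal genome chromosome names")
    want <- ceiling(sl / object@binWidth)
    got <- vapply(object@bins, length, integer(1))
    if (!all(got == want))
        return("bin vector lengths must equal ceiling(chrom_length / binWidth)")
    if (any(vapply(object@bins, function(b) any(!is.finite(b)) || any(b < 0),
                   logical(1))))
        return("bin counts must be finite and non-negative")
    if (length(object@totalAligned) != 1 || object@totalAligned < 0)
        return("totalAligned must be a single non-negative number")
    TRUE
})

#' SignalTrack: normalized ChIP signal on fixed-width bins
#'
#' Real-valued per-bin signal (for example ChIP minus input, or background
#' z-scores). Values may be negative for z-scored tracks; tracks produced
#' by [subtractInput()] are clipped at zero.
#'
#' @slot bins named list of per-chromosome numeric vectors.
#' @slot binWidth bin width in bp (20 bp by convention).
#' @slot normalization one of `"depth10M"`, `"chip_dna_factor"`,
#'   `"background_zscore"`.
#' @slot genome a [GenomeInfoDb::Seqinfo].
#' @export
setClass("SignalTrack",
    representation(bins = "list", binWidth = "integer",
                   normalization = "character", genome = "Seqinfo"))

setValidity("SignalTrack", function(object) {
    sl <- seqlengths(object@genome)
    if (!identical(names(object@bins), names(sl)))
        return("bin list names must equal genome chromosome names")
    want <- ceiling(sl / object@binWidth)
    got <- vapply(object@bins, length, integer(1))
    if (!all(got == want))
        return("bin vector lengths must equal ceiling(chrom_length / binWidth)")
    if (any(vapply(object@bins, function(b) any(!is.finite(b)), logical(1))))
        return("signal values must be finite")
    TRUE
})

#' GeneModels: gene bodies, exons and UTRs with strand-aware TSS
#'
#' A thin wrapper around a [GenomicRanges::GRanges] of typed features
#' (`gene`, `exon`, `five_prime_utr`, `three_prime_utr`), each carrying a
#' `gene_id`. The TSS is the first transcribed base: `start` on `+`
#' genes and `end` on `-` genes.
#'
#' @slot features GRanges with mcols `gene_id` and `type`.
#' @slot intergenicSlots GRanges of reserved gene-free intervals (used by
#'   the synthetic generator to place co-occupied region archetypes).
#' @export
setClass("GeneModels",
    representation(features = "GRanges", intergenicSlots = "GRanges"),
    prototype(intergenicSlots = GenomicRanges::GRanges()))

setValidity("GeneModels", function(object) {
    mc <- mcols(object@features)
    if (!all(c("gene_id", "type") %in% names(mc)))
        return("features must carry gene_id and type")
    ok_types <- c("gene", "exon", "five_prime_utr", "three_prime_utr")
    if (!all(mc$type %in% ok_types))
        return(paste("feature types must be in:", paste(ok_types, collapse = ", ")))
    g <- object@features[mc$type == "gene"]
    if (anyDuplicated(mcols(g)$gene_id))
        return("gene_id must be unique among gene features")
    if (!all(mc$gene_id %in% mcols(g)$gene_id))
        return("every exon/UTR must belong to a gene feature")
    TRUE
})

#' SimulationConfig: parameters of the synthetic study
#'
#' Encodes the planted structure: gene classes among derepressed genes
#' (C1 mark lost, C2 mark low, C3 mark retained), a global H3K27me3
#' depletion multiplier in the knockout, an H3K27ac gain at upregulated
#' genes, and negative-binomial expression with planted fold changes.
#'
#' @slot seed root seed for all generator randomness.
#' @slot nChroms,chromLength genome shape.
#' @slot nGenes number of gene models.
#' @slot classProportions named fractions over C1, C2, C3, down, unchanged;
#'   must sum to 1.
#' @slot backgroundRate expected reads per bin outside planted regions.
#' @slot enrichmentFold named per-mark fold (>= 1) at planted regions.
#' @slot globalDepletion multiplier in (0, 1] applied to knockout
#'   H3K27me3 peak rates at depleted loci.
#' @slot acGainFold H3K27ac fold gain (> 1) at upregulated genes in KO.
#' @slot exprMean,exprDispersion NB expression mean and dispersion.
#' @slot lfcUp,lfcDown planted log2 fold changes.
#' @slot nReps replicates per condition (>= 2).
#' @slot peakWidth planted promoter-peak width in bp.
#' @slot binWidth simulation bin width in bp.
#' @slot nEedRegions,eedRegionProportions count and E1/E2/E3 mixture of
#'   planted intergenic EED-bound archetype regions.
#' @slot unchangedPeakFraction fraction of unchanged genes that carry a
#'   (KO-depleted) H3K27me3 peak.
#' @slot backgroundDepletion if TRUE, the KO depletion also multiplies
#'   H3K27me3 background rates (off by default: models residual background).
#' @export
setClass("SimulationConfig",
    representation(seed = "integer", nChroms = "integer",
                   chromLength = "numeric", nGenes = "integer",
                   classProportions = "numeric", backgroundRate = "numeric",
                   enrichmentFold = "numeric", globalDepletion = "numeric",
                   acGainFold = "numeric", exprMean = "numeric",
                   exprDispersion = "numeric", lfcUp = "numeric",
                   lfcDown = "numeric", nReps = "integer",
                   peakWidth = "integer", binWidth = "integer",
                   nEedRegions = "integer", eedRegionProportions = "numeric",
                   unchangedPeakFraction = "numeric",
                   backgroundDepletion = "logical"))

setValidity("SimulationConfig", function(object) {
    cp <- object@classProportions
    if (!identical(sort(names(cp)), sort(c("C1", "C2", "C3", "down", "unchanged"))))
        return("classProportions must be named C1, C2, C3, down, unchanged")
    if (abs(sum(cp) - 1) > 1e-9)
        return("classProportions must sum to 1")
    if (any(cp < 0)) return("classProportions must be non-negative")
    if (object@backgroundRate <= 0) return("backgroundRate must be > 0")
    if (any(object@enrichmentFold < 1)) return("enrichmentFold must be >= 1")
    if (object@globalDepletion <= 0 || object@globalDepletion > 1)
        return("globalDepletion must be in (0, 1]")
    if (object@acGainFold <= 1) return("acGainFold must be > 1")
    if (object@exprMean <= 0 || object@exprDispersion <= 0)
        return("expression mean and dispersion must be > 0")
    if (object@nReps < 2) return("nReps must be >= 2")
    if (object@nChroms < 1 || object@chromLength < object@binWidth)
        return("genome shape invalid")
    ep <- object@eedRegionProportions
    if (!identical(sort(names(ep)), c("E1", "E2", "E3")) ||
        abs(sum(ep) - 1) > 1e-9)
        return("eedRegionProportions must be named E1, E2, E3 and sum to 1")
    if (object@unchangedPeakFraction < 0 || object@unchangedPeakFraction > 1)
        return("unchangedPeakFraction must be in [0, 1]")
    TRUE
})

#' SyntheticTruth: the planted parameters of a simulated study
#'
#' Everything downstream recovery is measured against: the class of every
#' gene, per-mark planted regions with condition-specific fold effects,
#' the global depletion factor, planted expression log2 fold changes, and
#' the archetype class of every planted EED-bound region. Also carries the
#' genome and gene models so coverage can be simulated from the object
#' alone.
#'
#' @export
setClass("SyntheticTruth",
    representation(geneClass = "factor", markRegions = "list",
                   depletionFactor = "numeric", exprLfc = "numeric",
                   eedRegions = "GRanges", config = "SimulationConfig",
                   models = "GeneModels", genome = "Seqinfo"))

setValidity("SyntheticTruth", function(object) {
    if (is.null(names(object@geneClass)) || anyDuplicated(names(object@geneClass)))
        return("geneClass must be uniquely named by gene")
    if (!all(levels(object@geneClass) %in% c("C1", "C2", "C3", "down", "unchanged")))
        return("gene classes must be C1, C2, C3, down or unchanged")
    for (mk in names(object@markRegions)) {
        mc <- mcols(object@markRegions[[mk]])
        if (!all(c("wt_fold", "ko_fold", "rescue_fold") %in% names(mc)))
            return("mark regions need wt_fold, ko_fold, rescue_fold")
    }
    me3 <- object@markRegions[["H3K27me3"]]
    if (!is.null(me3) && length(me3)) {
        cls <- object@geneClass[mcols(me3)$gene_id]
        strict <- object@depletionFactor < 1
        bad_c1 <- !is.na(cls) & cls == "C1" &
            (if (strict) !(mcols(me3)$ko_fold < mcols(me3)$wt_fold)
             else !(mcols(me3)$ko_fold <= mcols(me3)$wt_fold))
        bad_c3 <- !is.na(cls) & cls == "C3" &
            mcols(me3)$ko_fold != mcols(me3)$wt_fold
        if (any(bad_c1)) return("C1 regions must lose H3K27me3 in KO")
        if (any(bad_c3)) return("C3 regions must retain H3K27me3 in KO")
    }
    TRUE
})

## ---- generics and accessors -------------------------------------------

#' @export
setGeneric("trackBins", function(x) standardGeneric("trackBins"))
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
#' @export
setGeneric("totalAligned", function(x) standardGeneric("totalAligned"))
#' @export
setGeneric("trackGenome", function(x) standardGeneric("trackGenome"))
#' @export
setGeneric("normalizationTag", function(x) standardGeneric("normalizationTag"))
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))
#' @export
setGeneric("utrs", function(x) standardGeneric("utrs"))
#' @export
setGeneric("geneTSS", function(x) standardGeneric("geneTSS"))
#' @export
setGeneric("geneClass", function(x) standardGeneric("geneClass"))
#' @export
setGeneric("markRegions", function(x, mark) standardGeneric("markRegions"))
#' @export
setGeneric("eedRegions", function(x) standardGeneric("eedRegions"))
#' @export
setGeneric("exprLfc", function(x) standardGeneric("exprLfc"))
#' @export
setGeneric("depletionFactor", function(x) standardGeneric("depletionFactor"))

#' @describeIn CoverageTrack per-chromosome bin vectors
#' @param x a track object
#' @export
setMethod("trackBins", "CoverageTrack", function(x) x@bins)
#' @describeIn SignalTrack per-chromosome bin vectors
#' @param x a track object
#' @export
setMethod("trackBins", "SignalTrack", function(x) x@bins)
#' @describeIn CoverageTrack bin width in bp
#' @export
setMethod("binWidth", "CoverageTrack", function(x) x@binWidth)
#' @describeIn SignalTrack bin width in bp
#' @export
setMethod("binWidth", "SignalTrack", function(x) x@binWidth)
#' @describeIn CoverageTrack total aligned reads
#' @export
setMethod("totalAligned", "CoverageTrack", function(x) x@totalAligned)
#' @describeIn CoverageTrack genome Seqinfo
#' @export
setMethod("trackGenome", "CoverageTrack", function(x) x@genome)
#' @describeIn SignalTrack genome Seqinfo
#' @export
setMethod("trackGenome", "SignalTrack", function(x) x@genome)
#' @describeIn SignalTrack normalization tag
#' @export
setMethod("normalizationTag", "SignalTrack", function(x) x@normalization)

#' @describeIn GeneModels gene-body GRanges (one range per gene)
#' @param x a GeneModels object
#' @export
setMethod("genes", "GeneModels", function(x)
    x@features[mcols(x@features)$type == "gene"])
#' @describeIn GeneModels exon GRanges
#' @export
setMethod("exons", "GeneModels", function(x)
    x@features[mcols(x@features)$type == "exon"])
#' @describeIn GeneModels UTR GRanges (5' and 3')
#' @export
setMethod("utrs", "GeneModels", function(x)
    x@features[mcols(x@features)$type %in%
               c("five_prime_utr", "three_prime_utr")])

#' @describeIn GeneModels width-1 GRanges at each gene's strand-aware TSS
#' @export
setMethod("geneTSS", "GeneModels", function(x) {
    g <- genes(x)
    tss <- GenomicRanges::resize(g, width = 1L, fix = "start")
    names(tss) <- mcols(tss)$gene_id
    tss
})

#' @describeIn SyntheticTruth named factor of planted gene classes
#' @param x a SyntheticTruth object
#' @export
setMethod("geneClass", "SyntheticTruth", function(x) x@geneClass)
#' @describeIn SyntheticTruth planted regions for one mark (or all marks)
#' @param mark mark name; omit for the full list
#' @export
setMethod("markRegions", "SyntheticTruth", function(x, mark) {
    if (missing(mark)) return(x@markRegions)
    if (!mark %in% names(x@markRegions))
        stop2("unknown mark: ", mark)
    x@markRegions[[mark]]
})
#' @describeIn SyntheticTruth planted EED-bound archetype regions (E1-E3)
#' @export
setMethod("eedRegions", "SyntheticTruth", function(x) x@eedRegions)
#' @describeIn SyntheticTruth planted expression log2 fold changes
#' @export
setMethod("exprLfc", "SyntheticTruth", function(x) x@exprLfc)
#' @describeIn SyntheticTruth configured global depletion multiplier
#' @export
setMethod("depletionFactor", "SyntheticTruth", function(x) x@depletionFactor)

## ---- show methods -----------------------------------------------------

setMethod("show", "CoverageTrack", function(object) {
    cat("CoverageTrack:", length(object@bins), "chromosome(s),",
        object@binWidth, "bp bins\n")
    cat("  total aligned reads:", format(object@totalAligned, big.mark = ","),
        "\n")
    if (length(object@provenance))
        cat("  provenance:", paste(names(object@provenance), collapse = " -> "),
            "\n")
})

setMethod("show", "SignalTrack", function(object) {
    cat("SignalTrack:", length(object@bins), "chromosome(s),",
        object@binWidth, "bp bins, normalization:", object@normalization, "\n")
})

setMethod("show", "GeneModels", function(object) {
    cat("GeneModels:", length(genes(object)), "genes,",
        length(exons(object)), "exons,", length(utrs(object)), "UTRs\n")
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nGenes, "genes on", object@nChroms,
        "x", format(object@chromLength, big.mark = ","), "bp;",
        "depletion", object@globalDepletion, "; seed", object@seed, "\n")
    cat("  class proportions:",
        paste(names(object@classProportions), object@classProportions,
              sep = "=", collapse = " "), "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@geneClass), "genes (",
        paste(names(table(object@geneClass)), table(object@geneClass),
              sep = ":", collapse = " "), ")\n")
    cat("  marks:", paste(names(object@markRegions), collapse = ", "), "\n")
    cat("  EED archetype regions:", length(object@eedRegions),
        "; depletion factor:", object@depletionFactor, "\n")
})
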