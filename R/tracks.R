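## Coverage / signal track construction, I/O, and signal quantification.

#' Construct a CoverageTrack
#'
#' @param bins named list of per-chromosome numeric vectors of bin counts.
#' @param binWidth bin width in bp.
#' @param genome a [GenomeInfoDb::Seqinfo].
#' @param totalAligned total aligned reads; defaults to the sum of all bins.
#' @return a [CoverageTrack-class]
#' @export
CoverageTrack <- function(bins, binWidth, genome, totalAligned = NULL) {
    if (is.null(totalAligned))
        totalAligned <- sum(vapply(bins, sum, numeric(1)))
    new("CoverageTrack", bins = bins, binWidth = as.integer(binWidth),
        genome = genome, totalAligned = totalAligned)
}

#' Construct a SignalTrack
#'
#' @param bins named list of per-chromosome numeric vectors.
#' @param binWidth bin width in bp.
#' @param genome a [GenomeInfoDb::Seqinfo].
#' @param normalization normalization tag.
#' @return a [SignalTrack-class]
#' @export
SignalTrack <- function(bins, binWidth, genome,
                        normalization = c("depth10M", "chip_dna_factor",
                                          "background_zscore")) {
    new("SignalTrack", bins = bins, binWidth = as.integer(binWidth),
        genome = genome, normalization = match.arg(normalization))
}

## ---- bedGraph I/O -----------------------------------------------------

#' Read a bedGraph file into a binned CoverageTrack
#'
#' Dialect: 4 columns (chrom, start, end, value), 0-based half-open,
#' sorted and non-overlapping; `track`/`browser` lines are ignored. The
#' library size is taken from an optional `# total_aligned=<n>` header
#' line, otherwise from the sum of per-base values. Per-base values are
#' summed into fixed-width bins, so a record of value `v` spanning `L`
#' bases contributes `v * L` distributed over the bins it overlaps.
#'
#' @param path bedGraph file.
#' @param genome a [GenomeInfoDb::Seqinfo]; records must lie within it.
#' @param binWidth bin width in bp.
#' @return a [CoverageTrack-class]
#' @export
readBedGraph <- function(path, genome, binWidth) {
    lines <- readLines(path)
    total <- NA_real_
    hdr <- grep("^# *total_aligned=", lines, value = TRUE)
    if (length(hdr))
        total <- as.numeric(sub("^# *total_aligned=", "", hdr[1]))
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    sl <- seqlengths(genome)
    nb <- as.integer(ceiling(sl / binWidth))
    bins <- lapply(nb, numeric)
    names(bins) <- names(sl)
    if (any(keep)) {
        df <- read.table(text = lines[keep], sep = "\t",
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "numeric", "numeric",
                                        "numeric"))
        if (!all(df$chrom %in% names(sl)))
            stop2("bedGraph format error: unknown chromosome(s): ",
                  paste(unique(setdiff(df$chrom, names(sl))), collapse = ", "))
        if (any(df$start < 0) ||
            any(df$end > sl[df$chrom]) || any(df$start >= df$end))
            stop2("bedGraph format error: record out of genome bounds")
        for (chr in unique(df$chrom)) {
            d <- df[df$chrom == chr, , drop = FALSE]
            if (is.unsorted(d$start, strictly = TRUE) ||
                any(d$start[-1] < d$end[-nrow(d)]))
                stop2("bedGraph format error: records on ", chr,
                      " must be sorted and non-overlapping")
            # distribute value*bases into bins via per-base coverage
            cov <- coverage(IRanges(d$start + 1, d$end), weight = d$value,
                            width = sl[[chr]])
            starts <- seq(1L, by = binWidth, length.out = length(bins[[chr]]))
            ends <- pmin(starts + binWidth - 1L, sl[[chr]])
            bins[[chr]] <- as.numeric(viewSums(Views(cov, starts, ends)))
        }
    }
    CoverageTrack(bins, binWidth, genome,
                  totalAligned = if (is.na(total)) NULL else total)
}

#' Write a track to bedGraph
#'
#' Adjacent bins with equal values are merged into single records. A
#' `# total_aligned=` header is written for [CoverageTrack-class] inputs
#' so the library size round-trips.
#'
#' @param track a [CoverageTrack-class] or [SignalTrack-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path) {
    sl <- seqlengths(trackGenome(track))
    w <- binWidth(track)
    con <- file(path, "w")
    on.exit(close(con))
    if (is(track, "CoverageTrack"))
        writeLines(sprintf("# total_aligned=%.10g", totalAligned(track)), con)
    for (chr in names(sl)) {
        v <- trackBins(track)[[chr]]
        r <- Rle(v)
        ends0 <- cumsum(runLength(r)) * w
        starts0 <- ends0 - runLength(r) * w
        ends0 <- pmin(ends0, sl[[chr]])
        keep <- runValue(r) != 0
        if (!any(keep)) next
        writeLines(sprintf("%s\t%d\t%d\t%.10g", chr, starts0[keep],
                           ends0[keep], runValue(r)[keep] / w), con)
    }
    invisible(path)
}

## ---- normalization-by-depth and input subtraction ---------------------

#' Normalize a coverage track per 10 million aligned reads
#'
#' Every bin is multiplied by `1e7 / totalAligned`, after which the
#' recorded total is re-set to 1e7 by convention (making the operation
#' idempotent).
#'
#' @param track a [CoverageTrack-class] with positive `totalAligned`.
#' @return a depth-normalized [CoverageTrack-class]
#' @export
depthNormalize <- function(track) {
    tot <- totalAligned(track)
    if (tot <= 0) stop2("cannot depth-normalize a track with zero total reads")
    f <- 1e7 / tot
    bins <- lapply(trackBins(track), function(b) b * f)
    out <- CoverageTrack(bins, binWidth(track), trackGenome(track),
                         totalAligned = 1e7)
    out@provenance <- c(track@provenance, list(depth10M = f))
    out
}

#' ChIP-minus-input signal, clipped at zero
#'
#' Per bin, `max(chip - input, 0)`: ChIP reads minus input reads, kept
#' only where positive. Both tracks must share the genome and bin width
#' and should be depth-normalized first.
#'
#' @param chip,input matched [CoverageTrack-class] objects.
#' @return a [SignalTrack-class] tagged `depth10M`
#' @export
subtractInput <- function(chip, input) {
    if (binWidth(chip) != binWidth(input) ||
        !identical(seqlengths(trackGenome(chip)),
                   seqlengths(trackGenome(input))))
        stop2("chip and input tracks must share genome and bin width")
    bins <- mapply(function(a, b) pmax(a - b, 0), trackBins(chip),
                   trackBins(input), SIMPLIFY = FALSE)
    SignalTrack(bins, binWidth(chip), trackGenome(chip),
                normalization = "depth10M")
}

## ---- window quantification --------------------------------------------

# Bin values of `track` overlapping 0-based window [lo, hi) on chr,
# clipped to the chromosome.
.window_bins <- function(track, chr, lo, hi) {
    v <- trackBins(track)[[chr]]
    if (is.null(v)) stop2("unknown chromosome: ", chr)
    w <- binWidth(track)
    i1 <- max(1L, bin_of(max(lo, 0), w))
    i2 <- min(length(v), bin_of(hi - 1, w))
    if (i2 < i1) return(numeric(0))
    v[i1:i2]
}

#' Mean signal in a symmetric window around each gene's TSS
#'
#' For each gene, the strand-agnostic mean over bins overlapping
#' `[TSS - halfWidth, TSS + halfWidth)`; windows running off a chromosome
#' edge are clipped rather than dropped.
#'
#' @param signal a [SignalTrack-class] or [CoverageTrack-class].
#' @param models a [GeneModels-class].
#' @param halfWidth window half-width in bp; multiple of the bin width.
#' @return named numeric vector, one mean per gene
#' @export
windowSignal <- function(signal, models, halfWidth) {
    if (halfWidth %% binWidth(signal) != 0)
        stop2("halfWidth must be a multiple of the bin width")
    tss <- geneTSS(models)
    chrs <- as.character(seqnames(tss))
    if (!all(chrs %in% names(trackBins(signal))))
        stop2("gene on unknown chromosome")
    pos0 <- start(tss) - 1L  # 0-based TSS base
    out <- vapply(seq_along(tss), function(i) {
        b <- .window_bins(signal, chrs[i], pos0[i] - halfWidth,
                          pos0[i] + halfWidth)
        if (!length(b)) return(NA_real_)
        mean(b)
    }, numeric(1))
    setNames(out, names(tss))
}

#' Genome-wide distribution of signal in non-overlapping windows
#'
#' Sums track bins into consecutive fixed-width windows tiled over every
#' chromosome (the substrate of genome-wide violin plots); the trailing
#' partial window of each chromosome is included.
#'
#' @param track a track object.
#' @param window window width in bp; multiple of the bin width
#'   (default 1 kb).
#' @return numeric vector of per-window sums
#' @export
genomeWindowDistribution <- function(track, window = 1000L) {
    w <- binWidth(track)
    if (window %% w != 0) stop2("window must be a multiple of the bin width")
    k <- window %/% w
    unlist(lapply(trackBins(track), function(v) {
        grp <- (seq_along(v) - 1L) %/% k
        as.numeric(tapply(v, grp, sum))
    }), use.names = FALSE)
}

#' Metagene aggregation profile around anchor points
#'
#' Mean signal per offset across anchors, in bins of the track's width.
#' Each anchor contributes the `2 * halfWidth / step` bins centred on the
#' bin containing the anchor base; minus-strand anchors are reversed so
#' that offsets run in the direction of transcription.
#'
#' @param signal a [SignalTrack-class].
#' @param anchors data.frame with columns `chrom`, `pos` (0-based base)
#'   and `strand` (`+`/`-`), or a width-1 GRanges.
#' @param halfWidth profile half-width in bp.
#' @param step offset step; must equal the track bin width.
#' @return numeric vector of per-offset means, named by bp offset
#' @export
aggregateProfile <- function(signal, anchors, halfWidth, step = 20L) {
    if (step != binWidth(signal))
        stop2("step must equal the track bin width")
    if (is(anchors, "GRanges"))
        anchors <- data.frame(chrom = as.character(seqnames(anchors)),
                              pos = start(anchors) - 1L,
                              strand = as.character(strand(anchors)))
    if (nrow(anchors) == 0) stop2("empty anchor list")
    n <- halfWidth %/% step
    if (n < 1 || halfWidth %% step != 0)
        stop2("halfWidth must be a positive multiple of step")
    bins <- trackBins(signal)
    prof <- matrix(NA_real_, nrow(anchors), 2L * n)
    for (i in seq_len(nrow(anchors))) {
        v <- bins[[anchors$chrom[i]]]
        if (is.null(v)) stop2("anchor on unknown chromosome")
        b <- bin_of(anchors$pos[i], step)
        idx <- (b - n):(b + n - 1L)
        if (idx[1] < 1 || idx[length(idx)] > length(v))
            stop2("anchor window extends beyond the chromosome")
        vals <- v[idx]
        if (anchors$strand[i] == "-") vals <- rev(vals)
        prof[i, ] <- vals
    }
    setNames(colMeans(prof),
             as.character(seq(-halfWidth, halfWidth - step, by = step)))
}

#' Label peaks as TSS-proximal or distal
#'
#' A peak is proximal iff its interval intersects any gene's
#' `TSS +/- halfWidth` window; remaining peaks are distal.
#'
#' @param peaks GRanges of peaks.
#' @param models a [GeneModels-class].
#' @param halfWidth proximity half-width (default 5 kb).
#' @return factor with levels proximal, distal
#' @export
proximalDistalSplit <- function(peaks, models, halfWidth = 5000L) {
    tss <- geneTSS(models)
    win <- suppressWarnings(GenomicRanges::trim(
        GenomicRanges::resize(tss, width = 2L * halfWidth + 1L, fix = "center")))
    hit <- overlapsAny(peaks, win, ignore.strand = TRUE)
    factor(ifelse(hit, "proximal", "distal"), levels = c("proximal", "distal"))
}
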