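## Simplified broad-peak calling and peak-set analyses.

#' Call broad peaks from a ChIP/input track pair
#'
#' A deliberately simple, transparent broad-domain caller: each bin-width
#' window receives a one-sided Poisson p-value for its ChIP count against
#' a local rate `lambda = max(input window count, genome-wide input mean)`
#' scaled by the ratio of library sizes; p-values are BH-adjusted
#' genome-wide, significant windows closer than `mergeGap` are merged,
#' and merged intervals narrower than `minWidth` are dropped. The peak
#' score is the mean `log2(chip / lambda)` over its windows.
#'
#' The test operates on raw count tracks: the difference in sequencing
#' depth is folded into lambda rather than rescaling the counts, so the
#' Poisson tail probabilities stay calibrated.
#'
#' @param chip,input matched raw-count [CoverageTrack-class] objects.
#' @param fdr BH false-discovery-rate level (default 0.05).
#' @param minWidth minimum peak width in bp (default 200).
#' @param mergeGap maximum gap between significant windows merged into one
#'   peak (default 100 bp).
#' @return GRanges of peaks with mcols `score` (mean log2 enrichment) and
#'   `min_padj`
#' @export
callBroadPeaks <- function(chip, input, fdr = 0.05, minWidth = 200L,
                           mergeGap = 100L) {
    if (binWidth(chip) != binWidth(input) ||
        !identical(seqlengths(trackGenome(chip)),
                   seqlengths(trackGenome(input))))
        stop2("chip and input tracks must share genome and bin width")
    w <- binWidth(chip)
    cb <- unlist(trackBins(chip), use.names = FALSE)
    ib <- unlist(trackBins(input), use.names = FALSE)
    if (all(cb == 0) && all(ib == 0))
        return(GRanges(seqinfo = trackGenome(chip)))
    ratio <- totalAligned(chip) / totalAligned(input)
    lambda <- pmax(ib, mean(ib)) * ratio
    pval <- ppois(ceiling(cb) - 1, lambda, lower.tail = FALSE)
    padj <- p.adjust(pval, method = "BH")
    sig <- padj < fdr & cb > lambda
    if (!any(sig)) return(GRanges(seqinfo = trackGenome(chip)))

    nb <- vapply(trackBins(chip), length, integer(1))
    chr <- rep(names(nb), nb)
    idx <- unlist(lapply(nb, seq_len), use.names = FALSE)
    sl <- seqlengths(trackGenome(chip))
    sig_gr <- GRanges(chr[sig],
                      IRanges(start = (idx[sig] - 1L) * w + 1L,
                              end = pmin(idx[sig] * w, sl[chr[sig]])),
                      seqinfo = trackGenome(chip))
    peaks <- reduce(sig_gr, min.gapwidth = mergeGap + 1L)
    peaks <- peaks[width(peaks) >= minWidth]
    if (!length(peaks)) return(GRanges(seqinfo = trackGenome(chip)))

    # score each peak over its member windows
    win_gr <- GRanges(chr, IRanges(start = (idx - 1L) * w + 1L,
                                   end = pmin(idx * w, sl[chr])),
                      seqinfo = trackGenome(chip))
    hits <- findOverlaps(win_gr, peaks)
    grp <- factor(subjectHits(hits), levels = seq_along(peaks))
    le <- log2((cb[queryHits(hits)] + 0.5) / (lambda[queryHits(hits)] + 0.5))
    mcols(peaks)$score <- as.numeric(tapply(le, grp, mean))
    mcols(peaks)$min_padj <- as.numeric(tapply(padj[queryHits(hits)], grp, min))
    peaks
}

#' Venn partition of two peak sets
#'
#' A peak in one set is *shared* iff it intersects at least 1 bp of any
#' peak in the other set. Counting is per set (asymmetric): overlapping
#' peaks need not pair one-to-one, but within each set
#' `unique + shared = total`, matching how per-condition Venn totals are
#' reported.
#'
#' @param a,b GRanges peak sets on the same genome.
#' @return list with `counts` (a_only, a_shared, b_shared, b_only) and
#'   the corresponding interval lists
#' @export
vennPartition <- function(a, b) {
    a_sh <- overlapsAny(a, b, ignore.strand = TRUE)
    b_sh <- overlapsAny(b, a, ignore.strand = TRUE)
    list(counts = c(a_only = sum(!a_sh), a_shared = sum(a_sh),
                    b_shared = sum(b_sh), b_only = sum(!b_sh)),
         a_only = a[!a_sh], a_shared = a[a_sh],
         b_shared = b[b_sh], b_only = b[!b_sh])
}

#' Annotate peak centers by genomic feature
#'
#' The single center base of each peak -- `floor((start + end) / 2)` in
#' 0-based coordinates -- is assigned one category with precedence
#' promoter > UTR > exon > intron > intergenic. The promoter is
#' `TSS +/- promoterHalfwidth` (1 kb by default, a deliberately narrower
#' definition than the 5 kb proximal/distal rule).
#'
#' @param peaks GRanges of peaks.
#' @param models a [GeneModels-class] including exon/UTR structure.
#' @param promoterHalfwidth promoter half-width in bp (default 1 kb).
#' @return list with `category` (factor per peak) and `counts`
#' @export
annotatePeakCenter <- function(peaks, models, promoterHalfwidth = 1000L) {
    sl <- seqlengths(trackGenome_or_models(models))
    chrs <- as.character(seqnames(peaks))
    if (!all(chrs %in% names(sl)))
        stop2("peak center on unknown chromosome")
    center0 <- floor((start(peaks) - 1 + end(peaks)) / 2)
    centers <- GRanges(chrs, IRanges(center0 + 1L, center0 + 1L))

    tss <- geneTSS(models)
    prom <- suppressWarnings(GenomicRanges::trim(GenomicRanges::resize(
        tss, width = 2L * promoterHalfwidth + 1L, fix = "center")))
    in_prom <- overlapsAny(centers, prom, ignore.strand = TRUE)
    in_utr <- overlapsAny(centers, utrs(models), ignore.strand = TRUE)
    in_exon <- overlapsAny(centers, exons(models), ignore.strand = TRUE)
    in_gene <- overlapsAny(centers, genes(models), ignore.strand = TRUE)

    cat <- ifelse(in_prom, "promoter",
           ifelse(in_utr, "UTR",
           ifelse(in_exon, "exon",
           ifelse(in_gene, "intron", "intergenic"))))
    cat <- factor(cat, levels = c("promoter", "UTR", "exon", "intron",
                                  "intergenic"))
    list(category = cat, counts = table(cat))
}

# models carry seqinfo on their features GRanges
trackGenome_or_models <- function(models) seqinfo(models@features)

#' Assign each peak to the gene with the closest TSS
#'
#' Distance is measured from the peak center to each TSS; peaks farther
#' than `maxDist` from every TSS are unassigned. Ties are broken by the
#' lexicographically smaller gene id.
#'
#' @param peaks GRanges of peaks.
#' @param models a [GeneModels-class].
#' @param maxDist maximum center-to-TSS distance in bp (default 100 kb).
#' @return character vector of gene ids (NA where unassigned)
#' @export
assignPeakToGene <- function(peaks, models, maxDist = 1e5) {
    if (!length(peaks)) return(character(0))
    tss <- geneTSS(models)
    center0 <- floor((start(peaks) - 1 + end(peaks)) / 2)
    centers <- GRanges(seqnames(peaks), IRanges(center0 + 1L, center0 + 1L))
    search <- suppressWarnings(GenomicRanges::trim(GenomicRanges::resize(
        centers, width = 2L * maxDist + 1L, fix = "center")))
    hits <- findOverlaps(search, tss, ignore.strand = TRUE)
    out <- rep(NA_character_, length(peaks))
    if (length(hits)) {
        d <- abs(start(centers)[queryHits(hits)] - start(tss)[subjectHits(hits)])
        gid <- names(tss)[subjectHits(hits)]
        keep <- d <= maxDist
        df <- data.frame(q = queryHits(hits)[keep], d = d[keep],
                         gene = gid[keep])
        df <- df[order(df$q, df$d, df$gene), ]
        df <- df[!duplicated(df$q), ]
        out[df$q] <- df$gene
    }
    out
}

#' Percentages of a labeled partition
#'
#' `100 * count / total` per label, rounded half-even to 2 decimal
#' places -- the arithmetic behind statements like "1040 (49.86%) in
#' intergenic regions".
#'
#' @param counts named non-negative counts with positive total.
#' @return named numeric percentages (2 dp)
#' @export
partitionSummary <- function(counts) {
    counts <- unlist(counts)
    if (any(counts < 0)) stop2("counts must be non-negative")
    total <- sum(counts)
    if (total <= 0) stop2("total count must be positive")
    setNames(round(100 * counts / total, 2), names(counts))
}

## ---- k-means classification machinery ---------------------------------

# Deterministic, order-invariant k-means on log1p + column-standardized
# features. Rows are put into a canonical order before seeding so the
# restart stream does not depend on input row order; every row is then
# assigned to its nearest final centroid (ties -> lowest centroid index).
.kmeans_classify <- function(features, k, seed, nstart = 50L) {
    X <- as.matrix(features)
    if (any(!is.finite(X))) stop2("features must be finite")
    Xt <- log1p(pmax(X, 0))
    mu <- colMeans(Xt)
    sg <- apply(Xt, 2, sd)
    sg[sg == 0] <- 1
    Z <- sweep(sweep(Xt, 2, mu), 2, sg, "/")
    if (nrow(unique(Z)) < k)
        stop2("degenerate features: fewer than k distinct rows")
    ord <- do.call(order, as.data.frame(Z))
    km <- with_seed(seed,
        kmeans(Z[ord, , drop = FALSE], centers = k, nstart = nstart,
               iter.max = 200L))
    centers <- km$centers
    d2 <- vapply(seq_len(k), function(j)
        rowSums(sweep(Z, 2, centers[j, ])^2), numeric(nrow(Z)))
    cluster <- max.col(-d2, ties.method = "first")
    list(cluster = cluster, Z = Z)
}

#' Classify co-occupied regions into E1-E3 archetypes
#'
#' k-means (k = 3) on log1p-transformed, column-standardized region-level
#' signals for EED, H3K27me3, H3K27ac and HDAC2, with deterministic
#' seeding. Clusters are relabeled semantically by ascending mean
#' H3K27me3: E1 (EED/HDAC2/H3K27ac-marked, little H3K27me3), E2
#' (intermediate H3K27me3), E3 (strong H3K27me3, little H3K27ac).
#'
#' @param features matrix or data.frame, one row per region, with columns
#'   `EED`, `H3K27me3`, `H3K27ac`, `HDAC2`.
#' @param k number of classes (default 3).
#' @param seed deterministic seed for the k-means restarts.
#' @return list with `class` (factor E1/E2/E3 per region) and
#'   `centroids` (mean raw feature per class)
#' @export
classifyEedRegions <- function(features, k = 3L, seed = 1L) {
    features <- as.data.frame(features)
    need <- c("EED", "H3K27me3", "H3K27ac", "HDAC2")
    if (!all(need %in% names(features)))
        stop2("features must have columns ", paste(need, collapse = ", "))
    features <- features[, need]
    fit <- .kmeans_classify(features, k, seed)
    me3_mean <- tapply(features$H3K27me3, fit$cluster, mean)
    lab <- paste0("E", seq_len(k))
    relabel <- setNames(lab, names(sort(me3_mean)))
    cls <- factor(relabel[as.character(fit$cluster)], levels = lab)
    cent <- do.call(rbind, lapply(split(features, cls), colMeans))
    list(class = cls, centroids = cent)
}
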