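## Synthetic-data generator: genomes, gene models, planted mark regions,
## ChIP/input coverage and expression counts with known ground truth.
##
## The generator plants the structure the downstream analyses are meant
## to recover: upregulated gene classes C1 (H3K27me3 lost in KO), C2 (no
## H3K27me3 peak) and C3 (H3K27me3 retained); a global depletion factor
## for KO H3K27me3; an H3K27ac gain at upregulated genes that a rescue
## condition reverts while H3K27me3 stays at its KO level; EED promoter
## occupancy at C1-C3 genes; HDAC2 occupancy identical across conditions;
## and intergenic EED-bound archetype regions E1-E3.

#' Build a SimulationConfig
#'
#' Defaults encode the study conditions used throughout the package's
#' validation: 2000 genes on 2 x 14 Mb chromosomes, 20 bp bins,
#' background 5 reads/bin, 8-fold H3K27me3 peaks, global depletion 0.3,
#' 3-fold planted expression changes, 3 replicates per condition.
#'
#' @param seed root seed.
#' @param nChroms,chromLength,nGenes genome shape and gene count.
#' @param classProportions named fractions over C1, C2, C3, down,
#'   unchanged (sum 1).
#' @param backgroundRate expected reads per bin at background.
#' @param enrichmentFold named per-mark enrichment fold.
#' @param globalDepletion KO H3K27me3 multiplier in (0, 1].
#' @param acGainFold KO H3K27ac gain at upregulated genes.
#' @param exprMean,exprDispersion,lfcUp,lfcDown,nReps expression model.
#' @param peakWidth,binWidth planted peak width and bin width in bp.
#' @param nEedRegions,eedRegionProportions intergenic EED archetypes.
#' @param unchangedPeakFraction fraction of unchanged genes carrying a
#'   depleted H3K27me3 peak.
#' @param backgroundDepletion also deplete KO H3K27me3 background?
#' @return a [SimulationConfig-class]
#' @export
simulationConfig <- function(seed = 1L, nChroms = 2L, chromLength = 1.4e7,
                             nGenes = 2000L,
                             classProportions = c(C1 = 0.025, C2 = 0.030,
                                                  C3 = 0.031, down = 0.050,
                                                  unchanged = 0.864),
                             backgroundRate = 5,
                             enrichmentFold = c(H3K27me3 = 8, H3K27ac = 2,
                                                EED = 6, HDAC2 = 4),
                             globalDepletion = 0.3, acGainFold = 3,
                             exprMean = 100, exprDispersion = 0.1,
                             lfcUp = log2(3), lfcDown = -log2(3),
                             nReps = 3L, peakWidth = 2000L, binWidth = 20L,
                             nEedRegions = 300L,
                             eedRegionProportions = c(E1 = 0.588, E2 = 0.212,
                                                      E3 = 0.200),
                             unchangedPeakFraction = 0.5,
                             backgroundDepletion = FALSE) {
    new("SimulationConfig", seed = as.integer(seed),
        nChroms = as.integer(nChroms), chromLength = chromLength,
        nGenes = as.integer(nGenes), classProportions = classProportions,
        backgroundRate = backgroundRate, enrichmentFold = enrichmentFold,
        globalDepletion = globalDepletion, acGainFold = acGainFold,
        exprMean = exprMean, exprDispersion = exprDispersion,
        lfcUp = lfcUp, lfcDown = lfcDown, nReps = as.integer(nReps),
        peakWidth = as.integer(peakWidth), binWidth = as.integer(binWidth),
        nEedRegions = as.integer(nEedRegions),
        eedRegionProportions = eedRegionProportions,
        unchangedPeakFraction = unchangedPeakFraction,
        backgroundDepletion = backgroundDepletion)
}

#' Generate a genome and gene models
#'
#' Chromosomes are divided into fixed slots wide enough that every
#' gene's `TSS +/- 5 kb` window is disjoint from its neighbours'; genes
#' (and reserved intergenic slots for planted EED archetype regions) are
#' assigned to slots at random. Each gene gets a random strand, a body of
#' 2-8 kb, three exons and terminal UTRs. Deterministic given the config
#' seed.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `genome` (a [GenomeInfoDb::Seqinfo]) and `models`
#'   (a [GeneModels-class] whose `intergenicSlots` carry the reserved
#'   EED-region slots)
#' @export
makeGenome <- function(config) {
    validObject(config)
    slot_w <- config@peakWidth + 10000L
    chrom_names <- paste0("chr", seq_len(config@nChroms))
    sl <- setNames(rep(config@chromLength, config@nChroms), chrom_names)
    genome <- Seqinfo(seqnames = chrom_names, seqlengths = sl)
    per_chrom <- floor(config@chromLength / slot_w)
    total_slots <- per_chrom * config@nChroms
    need <- config@nGenes + config@nEedRegions
    if (need > total_slots)
        stop2("genome too small: ", need, " features need ", need,
              " slots of ", slot_w, " bp but only ", total_slots, " fit")

    with_seed(config@seed, {
        pick <- sample.int(total_slots, need)
        gene_slots <- sort(pick[seq_len(config@nGenes)])
        eed_slots <- sort(pick[-seq_len(config@nGenes)])

        slot_chr <- function(s) chrom_names[(s - 1L) %/% per_chrom + 1L]
        slot_center0 <- function(s)
            ((s - 1L) %% per_chrom) * slot_w + slot_w %/% 2L

        n <- config@nGenes
        gid <- sprintf("g%05d", seq_len(n))
        chr <- slot_chr(gene_slots)
        tss0 <- slot_center0(gene_slots) + sample(-500:500, n, replace = TRUE)
        strand <- sample(c("+", "-"), n, replace = TRUE)
        glen <- sample(2000:8000, n, replace = TRUE)

        # 1-based gene bodies; TSS base at tss0 (0-based)
        gstart <- ifelse(strand == "+", tss0 + 1L, tss0 + 1L - glen + 1L)
        gend <- gstart + glen - 1L
        gstart <- pmax(gstart, 1L)
        gend <- pmin(gend, as.integer(config@chromLength))

        feat <- list(GRanges(chr, IRanges(gstart, gend), strand = strand,
                             gene_id = gid, type = "gene",
                             seqinfo = genome))
        # exon/UTR structure in transcription direction: exon1 (300 bp,
        # first 100 bp 5'UTR), middle exon (400 bp), terminal exon
        # (300 bp, last 150 bp 3'UTR)
        add <- function(width, fix_start, type) {
            s <- ifelse(rep(fix_start, n) == (strand == "+"), gstart,
                        gend - width + 1L)
            GRanges(chr, IRanges(pmax(s, gstart),
                                 pmin(s + width - 1L, gend)),
                    strand = strand, gene_id = gid, type = type,
                    seqinfo = genome)
        }
        feat$exon1 <- add(300L, TRUE, "exon")
        feat$exon3 <- add(300L, FALSE, "exon")
        mid <- floor((gstart + gend) / 2)
        feat$exon2 <- GRanges(chr, IRanges(mid - 199L, mid + 200L),
                              strand = strand, gene_id = gid, type = "exon",
                              seqinfo = genome)
        feat$utr5 <- add(100L, TRUE, "five_prime_utr")
        feat$utr3 <- add(150L, FALSE, "three_prime_utr")
        features <- sort(do.call(c, unname(feat)), ignore.strand = TRUE)

        spare <- GRanges(slot_chr(eed_slots),
                         IRanges(slot_center0(eed_slots) -
                                 config@peakWidth %/% 2L + 1L,
                                 width = config@peakWidth),
                         seqinfo = genome)
        list(genome = genome,
             models = new("GeneModels", features = features,
                          intergenicSlots = spare))
    })
}

#' Plant ground truth on a genome
#'
#' Assigns gene classes by largest-remainder apportionment of the
#' configured proportions, then plants per-mark promoter regions
#' (width `peakWidth`, TSS-centered) with condition-specific folds:
#'
#' * H3K27me3: C1, down and a configured fraction of unchanged genes get
#'   peaks whose KO fold is `globalDepletion` times the WT fold; C3
#'   peaks keep their WT fold in KO; C2 genes get no peak. Rescue keeps
#'   KO folds (delayed re-expression does not restore the mark).
#' * H3K27ac: upregulated classes (C1-C3) gain `acGainFold` in KO;
#'   rescue restores the WT fold.
#' * EED: peaks at C1-C3 TSSs in WT (absent in KO, restored in rescue).
#' * HDAC2: peaks at C1-C3 TSSs, identical folds in all conditions.
#' * Intergenic EED archetype regions E1-E3 with class-specific
#'   EED/H3K27me3/H3K27ac/HDAC2 composition, constant across conditions.
#'
#' @param config a [SimulationConfig-class].
#' @param models the [GeneModels-class] from [makeGenome()].
#' @return a [SyntheticTruth-class]
#' @export
plantTruth <- function(config, models) {
    validObject(config)
    gid <- mcols(genes(models))$gene_id
    n <- length(gid)
    counts <- apportion(n, config@classProportions)
    cls <- with_seed(derive_seed(config@seed, 1L), {
        lab <- rep(names(counts), counts)
        setNames(factor(sample(lab), levels = names(counts)), gid)
    })

    tss <- geneTSS(models)[gid]
    half <- config@peakWidth %/% 2L
    prom <- function(ids) {
        t <- tss[ids]
        gr <- GRanges(as.character(seqnames(t)),
                      IRanges(pmax(start(t) - half + 1L, 1L),
                              width = 2L * half),
                      seqinfo = trackGenome_or_models(models))
        mcols(gr)$gene_id <- ids
        gr
    }
    fold <- function(gr, wt, ko, rescue) {
        mcols(gr)$wt_fold <- rep(wt, length.out = length(gr))
        mcols(gr)$ko_fold <- rep(ko, length.out = length(gr))
        mcols(gr)$rescue_fold <- rep(rescue, length.out = length(gr))
        gr
    }
    ef <- config@enrichmentFold
    dep <- config@globalDepletion

    c1 <- gid[cls == "C1"]; c2 <- gid[cls == "C2"]; c3 <- gid[cls == "C3"]
    dn <- gid[cls == "down"]; un <- gid[cls == "unchanged"]
    n_un_peak <- floor(length(un) * config@unchangedPeakFraction)
    un_peak <- with_seed(derive_seed(config@seed, 2L),
                         sample(un, n_un_peak))

    me3_parts <- list(
        fold(prom(c1), ef[["H3K27me3"]], dep * ef[["H3K27me3"]],
             dep * ef[["H3K27me3"]]),
        fold(prom(c3), ef[["H3K27me3"]], ef[["H3K27me3"]], ef[["H3K27me3"]]),
        fold(prom(dn), ef[["H3K27me3"]], dep * ef[["H3K27me3"]],
             dep * ef[["H3K27me3"]]),
        fold(prom(un_peak), ef[["H3K27me3"]], dep * ef[["H3K27me3"]],
             dep * ef[["H3K27me3"]]))
    me3 <- do.call(c, me3_parts)
    up <- c(c1, c2, c3)
    ac <- fold(prom(up), ef[["H3K27ac"]],
               config@acGainFold * ef[["H3K27ac"]], ef[["H3K27ac"]])
    # EED occupancy differs by class: strongest at retained Polycomb
    # domains (C3), weakest at weakly marked "poised" promoters (C2)
    eed_wt <- ef[["EED"]] *
        c(C1 = 1, C2 = 2 / 3, C3 = 4 / 3)[as.character(cls[up])]
    eed <- fold(prom(up), unname(eed_wt), 1, unname(eed_wt))
    hdac2 <- fold(prom(up), ef[["HDAC2"]], ef[["HDAC2"]], ef[["HDAC2"]])

    # intergenic EED-bound archetype regions
    spare <- models@intergenicSlots
    n_e <- min(config@nEedRegions, length(spare))
    e_counts <- apportion(n_e, config@eedRegionProportions)
    e_cls <- with_seed(derive_seed(config@seed, 3L),
                       factor(sample(rep(names(e_counts), e_counts)),
                              levels = c("E1", "E2", "E3")))
    e_reg <- spare[seq_len(n_e)]
    mcols(e_reg)$class <- e_cls
    mcols(e_reg)$region_id <- sprintf("e%04d", seq_len(n_e))
    # archetype composition (fold per mark; constant across conditions)
    arch <- list(E1 = c(EED = 6, H3K27me3 = 1, H3K27ac = 6, HDAC2 = 6),
                 E2 = c(EED = 8, H3K27me3 = 2, H3K27ac = 8, HDAC2 = 3),
                 E3 = c(EED = 8, H3K27me3 = 8, H3K27ac = 1, HDAC2 = 2))
    e_mark <- function(mark) {
        f <- vapply(as.character(e_cls), function(k) arch[[k]][[mark]],
                    numeric(1))
        keep <- f > 1
        if (!any(keep)) return(NULL)
        gr <- e_reg[keep]
        # E3 regions are broad: double width
        broad <- mcols(gr)$class == "E3"
        if (any(broad) && mark %in% c("EED", "H3K27me3")) {
            w2 <- width(gr[broad]) * 2L
            gr[broad] <- GenomicRanges::resize(gr[broad], width = w2,
                                               fix = "center")
        }
        mcols(gr)$gene_id <- NA_character_
        fold(gr, f[keep], f[keep], f[keep])
    }
    cat_gr <- function(a, b) if (is.null(b)) a else c(a, b[, names(mcols(a))])

    truth <- new("SyntheticTruth",
        geneClass = cls,
        markRegions = list(
            H3K27me3 = cat_gr(me3, e_mark("H3K27me3")),
            H3K27ac = cat_gr(ac, e_mark("H3K27ac")),
            EED = cat_gr(eed, e_mark("EED")),
            HDAC2 = cat_gr(hdac2, e_mark("HDAC2"))),
        depletionFactor = dep,
        exprLfc = setNames(ifelse(cls %in% c("C1", "C2", "C3"),
                                  config@lfcUp,
                                  ifelse(cls == "down", config@lfcDown, 0)),
                           gid),
        eedRegions = e_reg, config = config, models = models,
        genome = trackGenome_or_models(models))
    validObject(truth)
    truth
}

#' Simulate ChIP and input coverage for one mark and condition
#'
#' Independent Poisson counts per bin. The input rate is the background
#' rate everywhere; the ChIP rate is `backgroundRate * fold` at planted
#' bins (fractionally weighted at region edges), where the fold is the
#' region's condition-specific planted fold (`wt_fold`, `ko_fold` or
#' `rescue_fold`). The KO depletion of H3K27me3 is encoded in the
#' planted `ko_fold`s; the rescue condition keeps KO H3K27me3 folds but
#' restores H3K27ac to its WT fold. `depthScale` multiplies all rates.
#'
#' @param truth a [SyntheticTruth-class].
#' @param mark one of the marks in the truth object.
#' @param condition `"WT"`, `"KO"` or `"rescue"`.
#' @param depthScale sequencing-depth multiplier.
#' @param seed seed for this track pair.
#' @return list with `chip` and `input` [CoverageTrack-class] objects
#' @export
simulateChipCoverage <- function(truth, mark, condition = c("WT", "KO",
                                                            "rescue"),
                                 depthScale = 1, seed = 1L) {
    condition <- match.arg(condition)
    if (!mark %in% names(truth@markRegions))
        stop2("unknown mark: ", mark)
    config <- truth@config
    rate <- chipRates(truth, mark, condition)
    with_seed(seed, {
        chip_bins <- lapply(rate, function(r) rpois(length(r),
                                                    r * depthScale))
        input_bins <- lapply(rate, function(r)
            rpois(length(r), config@backgroundRate * depthScale))
        list(chip = CoverageTrack(lapply(chip_bins, as.numeric),
                                  config@binWidth, truth@genome),
             input = CoverageTrack(lapply(input_bins, as.numeric),
                                   config@binWidth, truth@genome))
    })
}

#' Expected per-bin ChIP rates for one mark and condition
#'
#' The noiseless rate field underlying [simulateChipCoverage()]; exposed
#' so tests can compare empirical means against configured rates.
#'
#' @inheritParams simulateChipCoverage
#' @return named list of per-chromosome rate vectors
#' @export
chipRates <- function(truth, mark, condition = c("WT", "KO", "rescue")) {
    condition <- match.arg(condition)
    config <- truth@config
    w <- config@binWidth
    sl <- seqlengths(truth@genome)
    bg <- config@backgroundRate
    base_bg <- if (condition != "WT" && mark == "H3K27me3" &&
                   config@backgroundDepletion) bg * config@globalDepletion
               else bg
    rate <- lapply(sl, function(L) rep(base_bg, ceiling(L / w)))
    regions <- truth@markRegions[[mark]]
    fcol <- switch(condition, WT = "wt_fold", KO = "ko_fold",
                   rescue = "rescue_fold")
    folds <- mcols(regions)[[fcol]]
    chrs <- as.character(seqnames(regions))
    s0 <- start(regions) - 1L
    e0 <- end(regions)
    for (i in seq_along(regions)) {
        v <- rate[[chrs[i]]]
        i1 <- bin_of(s0[i], w); i2 <- bin_of(e0[i] - 1L, w)
        i2 <- min(i2, length(v))
        frac <- rep(1, i2 - i1 + 1L)
        frac[1] <- frac[1] - (s0[i] - (i1 - 1L) * w) / w
        last <- i2 * w - e0[i]
        if (last > 0) frac[length(frac)] <- frac[length(frac)] - last / w
        extra <- bg * (folds[i] - 1) * frac
        rate[[chrs[i]]][i1:i2] <- v[i1:i2] + extra
    }
    rate
}

#' Simulate an expression count table
#'
#' Gene base means are log-normal around `exprMean`; counts are
#' negative-binomial with dispersion `exprDispersion`; KO means are the
#' WT means times `2^lfc` with the planted per-gene log2 fold change.
#'
#' @param truth a [SyntheticTruth-class].
#' @param config a [SimulationConfig-class] (defaults to the truth's).
#' @param seed seed (defaults to a stream derived from the config seed).
#' @return list with `counts` (genes x samples integer matrix) and
#'   `samples` (sample sheet data.frame)
#' @export
simulateExpressionCounts <- function(truth, config = truth@config,
                                     seed = derive_seed(config@seed, 4L)) {
    lfc <- truth@exprLfc
    n <- length(lfc)
    k <- config@nReps
    with_seed(seed, {
        base <- rlnorm(n, meanlog = log(config@exprMean), sdlog = 0.5)
        mu <- cbind(matrix(rep(base, k), ncol = k),
                    matrix(rep(base * 2^lfc, k), ncol = k))
        counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                                 size = 1 / config@exprDispersion),
                         nrow = n)
        rownames(counts) <- names(lfc)
        colnames(counts) <- c(paste0("WT_", seq_len(k)),
                              paste0("KO_", seq_len(k)))
        list(counts = counts,
             samples = data.frame(sample = colnames(counts),
                                  condition = rep(c("WT", "KO"), each = k)))
    })
}

## ---- fixture bundle I/O -----------------------------------------------

#' Write gene models to a GTF-like TSV
#'
#' Columns gene_id, chrom, strand, start, end, feature with 0-based
#' half-open coordinates.
#' @param models a [GeneModels-class].
#' @param path output file.
#' @return `path`, invisibly
#' @export
writeGeneModels <- function(models, path) {
    f <- models@features
    df <- data.frame(gene_id = mcols(f)$gene_id,
                     chrom = as.character(seqnames(f)),
                     strand = as.character(strand(f)),
                     start = start(f) - 1L, end = end(f),
                     feature = mcols(f)$type)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read gene models from a GTF-like TSV
#'
#' @param path file written by [writeGeneModels()].
#' @param genome a [GenomeInfoDb::Seqinfo].
#' @return a [GeneModels-class]
#' @export
readGeneModels <- function(path, genome) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     colClasses = c("character", "character", "character",
                                    "integer", "integer", "character"))
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                  strand = df$strand, seqinfo = genome)
    mcols(gr)$gene_id <- df$gene_id
    mcols(gr)$type <- df$feature
    new("GeneModels", features = gr)
}

#' Write a complete synthetic fixture bundle
#'
#' Emits standard text formats -- bedGraph per coverage track, BED6 per
#' planted region set, a GTF-like gene-model table, a TSV count matrix,
#' and a JSON truth object -- plus a manifest listing every file with
#' its md5 checksum. Identical inputs produce a byte-identical bundle.
#'
#' @param outdir output directory (created if needed).
#' @param truth a [SyntheticTruth-class].
#' @param tracks named list of [CoverageTrack-class] objects.
#' @param counts,samples from [simulateExpressionCounts()].
#' @return the manifest, invisibly (list of file = md5)
#' @export
writeFixtureBundle <- function(outdir, truth, tracks = list(),
                               counts = NULL, samples = NULL) {
    if (!dir.exists(outdir) &&
        !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
        stop2("cannot create output directory: ", outdir)
    files <- character(0)
    emit <- function(fn) { files <<- c(files, fn); fn }

    sl <- seqlengths(truth@genome)
    write.table(data.frame(chrom = names(sl), length = unname(sl)),
                emit(file.path(outdir, "genome.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeGeneModels(truth@models, emit(file.path(outdir, "genes.tsv")))
    for (nm in names(tracks))
        writeBedGraph(tracks[[nm]],
                      emit(file.path(outdir, paste0(nm, ".bedgraph"))))
    for (mk in names(truth@markRegions)) {
        r <- truth@markRegions[[mk]]
        df <- data.frame(chrom = as.character(seqnames(r)),
                         start = start(r) - 1L, end = end(r),
                         name = ifelse(is.na(mcols(r)$gene_id), ".",
                                       mcols(r)$gene_id),
                         score = mcols(r)$wt_fold, strand = ".")
        write.table(df, emit(file.path(outdir,
                                       paste0(mk, "_regions.bed"))),
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    }
    if (!is.null(counts)) {
        write.table(data.frame(gene = rownames(counts), counts,
                               check.names = FALSE),
                    emit(file.path(outdir, "counts.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(samples, emit(file.path(outdir, "samples.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    truth_json <- list(
        gene_class = as.list(setNames(as.character(truth@geneClass),
                                      names(truth@geneClass))),
        expr_lfc = as.list(truth@exprLfc),
        depletion_factor = truth@depletionFactor,
        eed_region_class = as.list(setNames(
            as.character(mcols(truth@eedRegions)$class),
            mcols(truth@eedRegions)$region_id)))
    jsonlite::write_json(truth_json,
                         emit(file.path(outdir, "truth.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- lapply(setNames(files, basename(files)), file_md5)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
}
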