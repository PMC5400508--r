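## End-to-end orchestration: simulate -> quantify -> normalize ->
## callpeaks -> classify -> report, with a flat config, deterministic
## seeds, and a checksummed run manifest.

#' Default pipeline configuration
#'
#' A flat list understood by [runPipeline()]: an output directory, a
#' root seed, simulation overrides (passed to [simulationConfig()]), and
#' analysis thresholds. `demo = TRUE` shrinks the simulated genome so the
#' whole pipeline runs in seconds.
#'
#' @param outdir output directory.
#' @param seed root seed; all stage randomness derives from it.
#' @param demo use the small demonstration genome?
#' @return named list
#' @export
pipelineConfig <- function(outdir, seed = 1L, demo = FALSE) {
    sim <- list(seed = seed)
    if (demo)
        sim <- c(sim, list(nChroms = 2L, chromLength = 1.2e6, nGenes = 150L,
                           nEedRegions = 45L,
                           classProportions = c(C1 = 0.08, C2 = 0.08,
                                                C3 = 0.09, down = 0.05,
                                                unchanged = 0.70)))
    list(outdir = outdir, seed = seed, simulation = sim,
         fdr = 0.05, fc_up = 1.5, fc_down = 0.67, de_alpha = 0.05,
         change_threshold = 0.67, tss_halfwidth = 500L,
         promoter_halfwidth = 1000L, proximal_halfwidth = 5000L,
         window = 1000L)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipelineConfig()].
#' @return named list
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop2("config error: missing input file: ", path)
    cfg <- yaml::read_yaml(path)
    base <- pipelineConfig(outdir = cfg$outdir %||% ".")
    cfg <- modifyList(base, cfg)
    cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validatePipelineConfig <- function(config) {
    num_in <- function(field, lo, hi, open = TRUE) {
        v <- config[[field]]
        bad <- !is.numeric(v) || length(v) != 1 ||
            (open && (v <= lo || v >= hi)) || (!open && (v < lo || v > hi))
        if (bad)
            stop2("config validation error: field '", field,
                  "' must be in ", if (open) "(" else "[", lo, ", ", hi,
                  if (open) ")" else "]")
    }
    if (is.null(config$outdir)) stop2("config validation error: field 'outdir' is required")
    num_in("fdr", 0, 1)
    num_in("de_alpha", 0, 1)
    num_in("change_threshold", 0, 1)
    if (!is.numeric(config$fc_up) || config$fc_up <= 1)
        stop2("config validation error: field 'fc_up' must be > 1")
    if (!is.numeric(config$fc_down) || config$fc_down <= 0 ||
        config$fc_down >= 1)
        stop2("config validation error: field 'fc_down' must be in (0, 1)")
    invisible(config)
}

.provenance_header <- function(config, stage) {
    sprintf("# chromdyn %s; seed=%d", stage, as.integer(config$seed))
}

.write_tsv <- function(df, path, header) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Stages: **simulate** (genome, truth, coverage, counts; fixture bundle
#' on disk), **quantify** (depth normalization, ChIP-minus-input signal,
#' TSS-window table, genome-wide window distributions), **normalize**
#' (ChIP-DNA-factor vs background z-score concordance for H3K27me3),
#' **callpeaks** (broad peaks per mark/condition, Venn partition, center
#' annotation, proximal/distal split, nearest-TSS assignment),
#' **classify** (NB differential expression, C1-C3 clustering of
#' upregulated genes, E1-E3 region classification, WT-quartile
#' stratification, rescue-ratio bins and scatter), and **report**
#' (summary tables via [generateReport()]).
#'
#' Reruns with the same config and seed are byte-identical. A stage
#' failure leaves earlier stage outputs intact and raises an error
#' naming the stage.
#'
#' @param config list from [pipelineConfig()] / [readPipelineConfig()],
#'   or a path to a YAML config.
#' @return path of the run manifest (JSON), invisibly
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readPipelineConfig(config)
    validatePipelineConfig(config)
    outdir <- config$outdir
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(seed = as.integer(config$seed), stages = list())
    run_stage <- function(name, fun) {
        files <- tryCatch(fun(),
                          error = function(e) stop2("stage '", name,
                                                    "' failed: ",
                                                    conditionMessage(e)))
        manifest$stages[[name]] <<- lapply(
            setNames(files, sub(paste0("^", outdir, "/?"), "", files)),
            file_md5)
        message("stage ", name, ": ", length(files), " file(s)")
    }
    env <- new.env(parent = emptyenv())

    run_stage("simulate", function() {
        sim_cfg <- do.call(simulationConfig, config$simulation)
        gm <- makeGenome(sim_cfg)
        truth <- plantTruth(sim_cfg, gm$models)
        specs <- list(c("H3K27me3", "WT"), c("H3K27me3", "KO"),
                      c("H3K27ac", "WT"), c("H3K27ac", "KO"),
                      c("H3K27ac", "rescue"), c("EED", "WT"),
                      c("HDAC2", "WT"), c("HDAC2", "KO"))
        tracks <- list()
        for (k in seq_along(specs)) {
            s <- specs[[k]]
            pair <- simulateChipCoverage(truth, s[1], s[2],
                                         seed = derive_seed(config$seed,
                                                            10L + k))
            tracks[[paste0(s[1], "_", s[2], "_chip")]] <- pair$chip
            if (s[1] == "H3K27me3")
                tracks[[paste0("input_", s[2])]] <- pair$input
        }
        tracks[["input_rescue"]] <- tracks[["input_KO"]]
        expr <- simulateExpressionCounts(truth)
        dir <- file.path(outdir, "simulate")
        writeFixtureBundle(dir, truth, tracks, expr$counts, expr$samples)
        env$truth <- truth; env$models <- gm$models
        env$tracks <- tracks; env$expr <- expr
        list.files(dir, full.names = TRUE)
    })

    run_stage("quantify", function() {
        dir <- file.path(outdir, "quantify")
        dir.create(dir, showWarnings = FALSE)
        hdr <- .provenance_header(config, "quantify")
        sig <- list()
        for (nm in names(env$tracks)) {
            if (!grepl("_chip$", nm)) next
            cond <- sub("^.*_(WT|KO|rescue)_chip$", "\\1", nm)
            sig[[sub("_chip$", "", nm)]] <- subtractInput(
                depthNormalize(env$tracks[[nm]]),
                depthNormalize(env$tracks[[paste0("input_", cond)]]))
        }
        env$signals <- sig
        tss_tab <- data.frame(gene = mcols(genes(env$models))$gene_id)
        for (nm in names(sig))
            tss_tab[[nm]] <- unname(windowSignal(sig[[nm]], env$models,
                                                 config$tss_halfwidth))
        f1 <- .write_tsv(tss_tab, file.path(dir, "tss_signal.tsv"), hdr)
        wd <- do.call(rbind, lapply(names(sig), function(nm) {
            d <- genomeWindowDistribution(sig[[nm]], config$window)
            data.frame(track = nm, median = median(d), mean = mean(d),
                       q90 = unname(quantile(d, 0.9)))
        }))
        f2 <- .write_tsv(wd, file.path(dir, "window_distribution.tsv"), hdr)
        env$tss_tab <- tss_tab
        c(f1, f2)
    })

    run_stage("normalize", function() {
        dir <- file.path(outdir, "normalize")
        dir.create(dir, showWarnings = FALSE)
        hdr <- .provenance_header(config, "normalize")
        wt <- env$tracks[["H3K27me3_WT_chip"]]
        ko <- env$tracks[["H3K27me3_KO_chip"]]
        # scheme A: depth per 10M, then rescale KO by the relative
        # ChIP-DNA amount (library-size ratio on the raw tracks)
        factor_ko <- totalAligned(ko) / totalAligned(wt)
        wtA <- depthNormalize(wt)
        koA <- applyChipDnaFactor(depthNormalize(ko), factor_ko)
        asSignal <- function(tr, tag) SignalTrack(trackBins(tr),
                                                  binWidth(tr),
                                                  trackGenome(tr), tag)
        # scheme B: z-score against the peak-free background, excluding
        # planted regions called in either condition
        excl <- reduce(c(GenomicRanges::granges(markRegions(env$truth,
                                                            "H3K27me3"))))
        zwt <- backgroundZscore(wt, excl)
        zko <- backgroundZscore(ko, excl)
        comp <- compareNormalizations(
            asSignal(wtA, "chip_dna_factor"), asSignal(koA, "chip_dna_factor"),
            zwt$signal, zko$signal, env$models,
            halfWidth = config$tss_halfwidth,
            threshold = config$change_threshold)
        f1 <- .write_tsv(comp$table, file.path(dir, "scheme_concordance.tsv"),
                         c(hdr, sprintf("# agreement=%.6f", comp$agreement),
                           sprintf("# chip_dna_factor=%.6g", factor_ko),
                           sprintf("# zscore_mu_wt=%.6g sigma_wt=%.6g",
                                   zwt$factors$mu, zwt$factors$sigma)))
        f1
    })

    run_stage("callpeaks", function() {
        dir <- file.path(outdir, "callpeaks")
        dir.create(dir, showWarnings = FALSE)
        hdr <- .provenance_header(config, "callpeaks")
        files <- character(0)
        peaks <- list()
        for (nm in c("H3K27me3_WT", "H3K27me3_KO", "H3K27ac_WT",
                     "H3K27ac_KO", "EED_WT", "HDAC2_WT")) {
            cond <- sub("^.*_", "", nm)
            pk <- callBroadPeaks(env$tracks[[paste0(nm, "_chip")]],
                                 env$tracks[[paste0("input_", cond)]],
                                 fdr = config$fdr)
            peaks[[nm]] <- pk
            df <- data.frame(chrom = as.character(seqnames(pk)),
                             start = start(pk) - 1L, end = end(pk),
                             name = sprintf("%s_peak%04d", nm,
                                            seq_along(pk)),
                             score = if (length(pk)) round(mcols(pk)$score,
                                                           4) else numeric(0),
                             strand = ".")
            fn <- file.path(dir, paste0(nm, "_peaks.bed"))
            write.table(df, fn, sep = "\t", quote = FALSE,
                        row.names = FALSE, col.names = FALSE)
            files <- c(files, fn)
        }
        env$peaks <- peaks
        venn <- vennPartition(peaks$H3K27me3_WT, peaks$H3K27me3_KO)
        f <- .write_tsv(data.frame(part = names(venn$counts),
                                   count = as.integer(venn$counts)),
                        file.path(dir, "venn_H3K27me3.tsv"), hdr)
        files <- c(files, f)
        ann <- annotatePeakCenter(peaks$H3K27me3_KO, env$models,
                                  config$promoter_halfwidth)
        pct <- partitionSummary(setNames(as.integer(ann$counts),
                                         names(ann$counts)))
        f <- .write_tsv(data.frame(category = names(ann$counts),
                                   count = as.integer(ann$counts),
                                   percent = unname(pct)),
                        file.path(dir, "ko_center_annotation.tsv"), hdr)
        files <- c(files, f)
        prox <- proximalDistalSplit(peaks$H3K27me3_KO, env$models,
                                    config$proximal_halfwidth)
        gene_of <- assignPeakToGene(peaks$H3K27me3_KO, env$models)
        f <- .write_tsv(data.frame(peak = seq_along(prox),
                                   location = as.character(prox),
                                   gene = ifelse(is.na(gene_of), ".",
                                                 gene_of)),
                        file.path(dir, "ko_peak_assignment.tsv"), hdr)
        c(files, f)
    })

    run_stage("classify", function() {
        dir <- file.path(outdir, "classify")
        dir.create(dir, showWarnings = FALSE)
        hdr <- .provenance_header(config, "classify")
        de <- callDifferentialGenes(env$expr$counts,
                                    env$expr$samples$condition == "KO",
                                    fcUp = config$fc_up,
                                    fcDown = config$fc_down,
                                    alpha = config$de_alpha)
        f1 <- .write_tsv(within(de, {
                             log2FC <- round(log2FC, 4)
                             baseMean <- round(baseMean, 3)
                             pvalue <- signif(pvalue, 4)
                             padj <- signif(padj, 4)
                         }),
                         file.path(dir, "differential_expression.tsv"), hdr)
        tt <- env$tss_tab
        sig_of <- function(col) setNames(tt[[col]], tt$gene)
        up <- de$gene[de$status == "up"]
        # cluster only EED-target upregulated genes: k = 3 presumes the
        # three mark-dynamics archetypes, which DE false positives with
        # no EED occupancy do not fit
        eed_pk <- env$peaks$EED_WT
        if (length(eed_pk)) {
            tss <- geneTSS(env$models)[up]
            win <- suppressWarnings(GenomicRanges::trim(
                GenomicRanges::resize(tss, width = 10001L, fix = "center")))
            up <- up[overlapsAny(win, eed_pk, ignore.strand = TRUE)]
        }
        if (length(up) < 8) {
            message("too few DE-upregulated genes (", length(up),
                    "); using planted upregulated set for clustering")
            up <- names(geneClass(env$truth))[geneClass(env$truth) %in%
                                              c("C1", "C2", "C3")]
        }
        cl <- clusterUpregulatedGenes(up, sig_of("H3K27me3_WT"),
                                      sig_of("H3K27me3_KO"),
                                      sig_of("EED_WT"),
                                      seed = derive_seed(config$seed, 30L))
        f2 <- .write_tsv(data.frame(gene = names(cl$class),
                                    cluster = as.character(cl$class)),
                         file.path(dir, "up_gene_clusters.tsv"), hdr)
        er <- eedRegions(env$truth)
        feats <- do.call(cbind, lapply(
            c(EED = "EED_WT", H3K27me3 = "H3K27me3_WT",
              H3K27ac = "H3K27ac_WT", HDAC2 = "HDAC2_WT"),
            function(nm) regionSignal(env$signals[[nm]], er)))
        ecl <- classifyEedRegions(feats,
                                  seed = derive_seed(config$seed, 31L))
        f3 <- .write_tsv(data.frame(region = mcols(er)$region_id,
                                    class = as.character(ecl$class),
                                    truth = as.character(mcols(er)$class)),
                         file.path(dir, "eed_region_classes.tsv"), hdr)
        qt <- stratifyByWtQuartiles(sig_of("H3K27me3_WT")[up],
                                    sig_of("H3K27me3_KO")[up])
        f4 <- .write_tsv(within(qt, p <- signif(p, 4)),
                         file.path(dir, "wt_quartile_stratification.tsv"),
                         hdr)
        rb <- rescueRatioBins(pmax(sig_of("H3K27ac_KO")[up], 0),
                              pmax(sig_of("H3K27ac_rescue")[up], 0))
        f5 <- .write_tsv(data.frame(bin = names(rb$counts),
                                    count = as.integer(rb$counts)),
                         file.path(dir, "rescue_ratio_bins.tsv"), hdr)
        eps <- 1e-3
        sc <- rescueChangeScatter(
            (pmax(sig_of("H3K27ac_KO")[up], 0) + eps) /
                (pmax(sig_of("H3K27ac_WT")[up], 0) + eps),
            (pmax(sig_of("H3K27ac_KO")[up], 0) + eps) /
                (pmax(sig_of("H3K27ac_rescue")[up], 0) + eps))
        f6 <- .write_tsv(within(sc$table, {
                             log2_lof <- round(log2_lof, 4)
                             log2_rescue <- round(log2_rescue, 4)
                         }),
                         file.path(dir, "rescue_change_scatter.tsv"),
                         c(hdr, sprintf("# spearman_rho=%.6f", sc$rho)))
        c(f1, f2, f3, f4, f5, f6)
    })

    manifest_path <- file.path(outdir, "run_manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
    report_files <- generateReport(manifest_path)
    manifest$stages[["report"]] <- lapply(
        setNames(report_files,
                 sub(paste0("^", outdir, "/?"), "", report_files)),
        file_md5)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(manifest_path)
}

#' Mean signal over arbitrary regions
#'
#' Companion to [windowSignal()] for non-TSS anchors: the mean of track
#' bins overlapping each region.
#'
#' @param signal a track object.
#' @param regions GRanges.
#' @return numeric vector, one mean per region
#' @export
regionSignal <- function(signal, regions) {
    chrs <- as.character(seqnames(regions))
    vapply(seq_along(regions), function(i) {
        b <- .window_bins(signal, chrs[i], start(regions)[i] - 1L,
                          end(regions)[i])
        if (!length(b)) NA_real_ else mean(b)
    }, numeric(1))
}

#' Generate summary report tables from a run manifest
#'
#' Reads the stage outputs listed in the manifest and writes the
#' figure-substrate summary tables: Venn counts, peak-center categories
#' with percentages, C1-C3 and E1-E3 class sizes, quartile summaries,
#' differential-expression counts, rescue bins, and a plain-text
#' overview. Regeneration is idempotent.
#'
#' @param manifestPath path to `run_manifest.json` from [runPipeline()].
#' @return character vector of written files
#' @export
generateReport <- function(manifestPath) {
    manifest <- jsonlite::read_json(manifestPath)
    outdir <- dirname(manifestPath)
    need <- c("simulate", "quantify", "normalize", "callpeaks", "classify")
    missing <- setdiff(need, names(manifest$stages))
    if (length(missing))
        stop2("incomplete manifest; missing stage(s): ",
              paste(missing, collapse = ", "))
    dir <- file.path(outdir, "report")
    dir.create(dir, showWarnings = FALSE)
    hdr <- sprintf("# chromdyn report; seed=%d", manifest$seed)
    rd <- function(stage, file)
        read.table(file.path(outdir, stage, file), sep = "\t", header = TRUE,
                   comment.char = "#")
    files <- character(0)
    put <- function(df, name) {
        f <- .write_tsv(df, file.path(dir, name), hdr)
        files <<- c(files, f)
        f
    }
    venn <- rd("callpeaks", "venn_H3K27me3.tsv")
    put(venn, "venn_counts.tsv")
    ann <- rd("callpeaks", "ko_center_annotation.tsv")
    put(ann, "center_categories.tsv")
    de <- rd("classify", "differential_expression.tsv")
    put(as.data.frame(table(status = de$status)), "de_counts.tsv")
    cl <- rd("classify", "up_gene_clusters.tsv")
    put(as.data.frame(table(cluster = cl$cluster)), "c_sizes.tsv")
    ec <- rd("classify", "eed_region_classes.tsv")
    put(as.data.frame(table(class = ec$class)), "e_sizes.tsv")
    put(rd("classify", "wt_quartile_stratification.tsv"), "quartiles.tsv")
    put(rd("classify", "rescue_ratio_bins.tsv"), "rescue_bins.tsv")
    put(rd("quantify", "window_distribution.tsv"),
        "window_distribution.tsv")
    sm <- c(hdr,
            sprintf("H3K27me3 peaks: WT %d (unique %d), KO %d (unique %d), shared (per KO) %d",
                    venn$count[venn$part == "a_only"] +
                        venn$count[venn$part == "a_shared"],
                    venn$count[venn$part == "a_only"],
                    venn$count[venn$part == "b_only"] +
                        venn$count[venn$part == "b_shared"],
                    venn$count[venn$part == "b_only"],
                    venn$count[venn$part == "b_shared"]),
            sprintf("DE genes: %d up, %d down of %d tested",
                    sum(de$status == "up"), sum(de$status == "down"),
                    nrow(de)),
            sprintf("C clusters: %s",
                    paste(names(table(cl$cluster)), table(cl$cluster),
                          sep = "=", collapse = " ")),
            sprintf("E classes: %s",
                    paste(names(table(ec$class)), table(ec$class),
                          sep = "=", collapse = " ")))
    f <- file.path(dir, "summary.txt")
    writeLines(sm, f)
    files <- c(files, f)
    files
}
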