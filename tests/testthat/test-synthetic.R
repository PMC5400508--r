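test_that("genome generation places genes with disjoint TSS windows", {
    cfg <- simulationConfig(seed = 4, nChroms = 1L, chromLength = 1e6,
                            nGenes = 10L, nEedRegions = 5L)
    gm <- makeGenome(cfg)
    expect_equal(length(genes(gm$models)), 10L)
    win <- GenomicRanges::resize(geneTSS(gm$models), width = 10001L,
                                 fix = "center")
    expect_true(GenomicRanges::isDisjoint(win, ignore.strand = TRUE))
    expect_setequal(unique(as.character(strand(genes(gm$models)))),
                    c("+", "-"))
    # deterministic: same seed twice -> identical annotation on disk
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    writeGeneModels(gm$models, f1)
    writeGeneModels(makeGenome(cfg)$models, f2)
    expect_identical(readLines(f1), readLines(f2))
    # pigeonhole: more genes than slots
    expect_error(makeGenome(simulationConfig(nChroms = 1L,
                                             chromLength = 1e6,
                                             nGenes = 1000L)),
                 "too small")
})

test_that("planted truth matches configured class proportions exactly", {
    cfg <- simulationConfig(seed = 8, nChroms = 1L, chromLength = 1.3e6,
                            nGenes = 100L, nEedRegions = 6L,
                            classProportions = c(C1 = 0.1, C2 = 0.1,
                                                 C3 = 0.1, down = 0.1,
                                                 unchanged = 0.6))
    truth <- plantTruth(cfg, makeGenome(cfg)$models)
    expect_equal(unname(table(geneClass(truth))[c("C1", "C2", "C3", "down",
                                                  "unchanged")]),
                 array(c(10L, 10L, 10L, 10L, 60L)), ignore_attr = TRUE)
    expect_equal(length(geneClass(truth)), 100L)  # every gene classified

    me3 <- markRegions(truth, "H3K27me3")
    mc <- S4Vectors::mcols(me3)[!is.na(S4Vectors::mcols(me3)$gene_id), ]
    cls <- geneClass(truth)[mc$gene_id]
    # C1 regions lose the mark; C3 regions keep it; C2 genes have none
    expect_true(all(mc$ko_fold[cls == "C1"] < mc$wt_fold[cls == "C1"]))
    expect_true(all(mc$ko_fold[cls == "C3"] == mc$wt_fold[cls == "C3"]))
    expect_false(any(geneClass(truth)[mc$gene_id[!is.na(mc$gene_id)]] ==
                     "C2"))
    expect_equal(unique(mc$ko_fold[cls == "C1"]),
                 cfg@globalDepletion * unique(mc$wt_fold[cls == "C1"]))

    # HDAC2 occupancy identical in all conditions
    h <- S4Vectors::mcols(markRegions(truth, "HDAC2"))
    expect_equal(h$wt_fold, h$ko_fold)
    expect_equal(h$wt_fold, h$rescue_fold)

    # rescue keeps KO H3K27me3 but restores WT H3K27ac
    expect_equal(mc$rescue_fold, mc$ko_fold)
    a <- S4Vectors::mcols(markRegions(truth, "H3K27ac"))
    gene_peaks <- !is.na(a$gene_id)
    expect_equal(a$rescue_fold[gene_peaks], a$wt_fold[gene_peaks])
    expect_true(all(a$ko_fold[gene_peaks] > a$wt_fold[gene_peaks]))

    expect_error(simulationConfig(classProportions = c(C1 = 0.5, C2 = 0.2,
                                                       C3 = 0.2, down = 0.2,
                                                       unchanged = 0.2)),
                 "sum to 1")
})

test_that("coverage simulation matches configured rates and determinism", {
    # flat config: no enrichment, no depletion -> WT and KO identical in
    # distribution, mean ~= background rate (>= 1e5 bins, 3 SE)
    cfg <- simulationConfig(seed = 5, nChroms = 1L, chromLength = 2.4e6,
                            nGenes = 50L, nEedRegions = 0L,
                            enrichmentFold = c(H3K27me3 = 1, H3K27ac = 1,
                                               EED = 1, HDAC2 = 1),
                            globalDepletion = 1)
    truth <- plantTruth(cfg, makeGenome(cfg)$models)
    wt <- simulateChipCoverage(truth, "H3K27me3", "WT", seed = 21)
    ko <- simulateChipCoverage(truth, "H3K27me3", "KO", seed = 22)
    nb <- length(trackBins(wt$chip)$chr1)
    expect_gte(nb, 1e5)
    se <- sqrt(5 / nb)
    expect_lt(abs(mean(trackBins(wt$chip)$chr1) - 5), 3 * se)
    expect_lt(abs(mean(trackBins(ko$chip)$chr1) - 5), 3 * se)
    expect_lt(abs(mean(trackBins(wt$input)$chr1) - 5), 3 * se)
    # same seed -> identical tracks
    wt2 <- simulateChipCoverage(truth, "H3K27me3", "WT", seed = 21)
    expect_identical(trackBins(wt2$chip), trackBins(wt$chip))
    # doubling depth doubles totals in expectation
    deep <- simulateChipCoverage(truth, "H3K27me3", "WT", depthScale = 2,
                                 seed = 23)
    expect_equal(totalAligned(deep$chip) / totalAligned(wt$chip), 2,
                 tolerance = 0.01)
    expect_error(simulateChipCoverage(truth, "H3K9me3", "WT"),
                 "unknown mark")

    # planted-peak bins reach backgroundRate * fold on average
    cfg2 <- small_config(seed = 6)
    truth2 <- plantTruth(cfg2, makeGenome(cfg2)$models)
    rates <- chipRates(truth2, "H3K27me3", "WT")
    wtp <- simulateChipCoverage(truth2, "H3K27me3", "WT", seed = 31)
    peak_bins <- which(rates$chr1 == 40)
    emp <- mean(trackBins(wtp$chip)$chr1[peak_bins])
    expect_lt(abs(emp - 40), 3 * sqrt(40 / length(peak_bins)))
    # KO rates at C1 promoters reflect the global depletion
    ratesk <- chipRates(truth2, "H3K27me3", "KO")
    c1 <- names(geneClass(truth2))[geneClass(truth2) == "C1"][1]
    tss <- geneTSS(truth2@models)[c1]
    b <- (start(tss) - 1) %/% 20 + 1
    expect_equal(ratesk[[as.character(seqnames(tss))]][b], 5 * 8 * 0.3)
})

test_that("expression counts follow the planted NB model", {
    cfg <- simulationConfig(seed = 9, nChroms = 1L, chromLength = 1.3e6,
                            nGenes = 100L, nEedRegions = 0L, nReps = 50L,
                            classProportions = c(C1 = 0.3, C2 = 0, C3 = 0,
                                                 down = 0, unchanged = 0.7))
    truth <- plantTruth(cfg, makeGenome(cfg)$models)
    expr <- simulateExpressionCounts(truth)
    expect_equal(dim(expr$counts), c(100L, 100L))
    ko <- expr$samples$condition == "KO"
    ratio <- rowMeans(expr$counts[, ko]) / rowMeans(expr$counts[, !ko])
    planted_up <- geneClass(truth) == "C1"
    expect_equal(median(ratio[planted_up]), 3, tolerance = 0.15)
    expect_equal(median(ratio[!planted_up]), 1, tolerance = 0.1)

    # dispersion -> 0 limit: variance ~= mean (Poisson limit)
    cfg2 <- simulationConfig(seed = 10, nChroms = 1L, chromLength = 1.3e6,
                             nGenes = 100L, nEedRegions = 0L, nReps = 200L,
                             exprDispersion = 1e-6)
    truth2 <- plantTruth(cfg2, makeGenome(cfg2)$models)
    expr2 <- simulateExpressionCounts(truth2)
    wtc <- expr2$counts[, expr2$samples$condition == "WT"]
    vm <- apply(wtc, 1, var) / rowMeans(wtc)
    expect_equal(median(vm), 1, tolerance = 0.1)
})

test_that("fixture bundles round-trip and have faithful checksums", {
    cfg <- simulationConfig(seed = 12, nChroms = 1L, chromLength = 6e5,
                            nGenes = 20L, nEedRegions = 6L)
    gm <- makeGenome(cfg)
    truth <- plantTruth(cfg, gm$models)
    pair <- simulateChipCoverage(truth, "H3K27me3", "WT", seed = 41)
    expr <- simulateExpressionCounts(truth)
    d1 <- withr::local_tempdir()
    man1 <- writeFixtureBundle(d1, truth,
                               tracks = list(me3_wt = pair$chip,
                                             input_wt = pair$input),
                               counts = expr$counts, samples = expr$samples)
    # bedGraph round-trip reproduces the in-memory track
    back <- readBedGraph(file.path(d1, "me3_wt.bedgraph"), truth@genome,
                         binWidth(pair$chip))
    expect_equal(trackBins(back), trackBins(pair$chip))
    # truth JSON reload reproduces the gene-class mapping exactly
    tj <- jsonlite::read_json(file.path(d1, "truth.json"))
    expect_equal(unlist(tj$gene_class),
                 setNames(as.character(geneClass(truth)),
                          names(geneClass(truth))))
    # gene models round-trip
    gm2 <- readGeneModels(file.path(d1, "genes.tsv"), truth@genome)
    expect_equal(start(geneTSS(gm2)), start(geneTSS(gm$models)))
    # regenerating the bundle is byte-identical
    d2 <- withr::local_tempdir()
    man2 <- writeFixtureBundle(d2, truth,
                               tracks = list(me3_wt = pair$chip,
                                             input_wt = pair$input),
                               counts = expr$counts, samples = expr$samples)
    expect_identical(man1, man2)
    # checksums change iff content changes
    fn <- file.path(d1, "counts.tsv")
    md5_before <- unname(tools::md5sum(fn))
    cat("x\n", file = fn, append = TRUE)
    expect_false(unname(tools::md5sum(fn)) == md5_before)
})
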