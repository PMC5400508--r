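test_that("broad-peak caller recovers planted regions and merges windows", {
    set.seed(101)
    g <- toy_genome(c(chr1 = 200000L))
    nb <- 10000L
    rate <- rep(5, nb)
    planted <- list(c(2001L, 4000L), c(50001L, 52000L), c(120001L, 122000L))
    for (p in planted) rate[(p[1] %/% 20 + 1):(p[2] %/% 20)] <- 40  # 8-fold
    chip <- toy_track(list(chr1 = rpois(nb, rate)), genome = g)
    input <- toy_track(list(chr1 = rpois(nb, 5)), genome = g)
    pk <- callBroadPeaks(chip, input)
    expect_equal(length(pk), 3L)
    truth_gr <- GRanges("chr1", IRanges(sapply(planted, `[`, 1) + 1,
                                        sapply(planted, `[`, 2)))
    ov <- sum(width(GenomicRanges::intersect(pk, truth_gr)))
    expect_gte(ov / sum(width(truth_gr)), 0.9)  # base-level recall
    expect_true(all(S4Vectors::mcols(pk)$score > 1))

    # null pair: no calls expected
    null_pk <- callBroadPeaks(toy_track(list(chr1 = rpois(nb, 5)),
                                        genome = g),
                              toy_track(list(chr1 = rpois(nb, 5)),
                                        genome = g))
    expect_lte(length(null_pk), 1L)

    # two adjacent significant windows merge even with mergeGap = 0
    chip2 <- toy_track(list(chr1 = c(rep(0, 40), 500, 500, rep(0, 58))),
                       genome = toy_genome(c(chr1 = 2000L)), total = 500)
    input2 <- toy_track(list(chr1 = rep(5, 100)),
                        genome = toy_genome(c(chr1 = 2000L)), total = 500)
    pk2 <- callBroadPeaks(chip2, input2, mergeGap = 0L, minWidth = 40L)
    expect_equal(length(pk2), 1L)
    expect_equal(width(pk2), 40L)

    # all-zero chip and input -> empty set
    z <- toy_track(list(chr1 = rep(0, 100)),
                   genome = toy_genome(c(chr1 = 2000L)), total = 1)
    expect_length(callBroadPeaks(z, z), 0L)
})

test_that("Venn partition counts conserve per-set totals", {
    a <- GRanges("chr1", IRanges(c(1, 100, 300), width = 50))
    b <- GRanges("chr1", IRanges(c(120, 700), width = 50))
    v <- vennPartition(a, b)
    expect_equal(unname(v$counts),
                 c(2L, 1L, 1L, 1L))  # a_only, a_shared, b_shared, b_only
    expect_equal(v$counts[["a_only"]] + v$counts[["a_shared"]], length(a))
    expect_equal(v$counts[["b_only"]] + v$counts[["b_shared"]], length(b))
    # identical and disjoint sets
    expect_equal(unname(vennPartition(a, a)$counts), c(0L, 3L, 3L, 0L))
    expect_equal(unname(vennPartition(a, shift(a, 10000))$counts),
                 c(3L, 0L, 0L, 3L))
    # random toys vs exhaustive pairwise-intersection oracle
    set.seed(111)
    for (rep in 1:5) {
        ra <- GRanges("chr1", IRanges(sample(1:5000, 20), width = 80))
        rb <- GRanges("chr1", IRanges(sample(1:5000, 15), width = 60))
        v2 <- vennPartition(ra, rb)
        expect_equal(sum(oracle_overlaps_any(ra, rb)),
                     unname(v2$counts[["a_shared"]]))
        expect_equal(sum(oracle_overlaps_any(rb, ra)),
                     unname(v2$counts[["b_shared"]]))
    }
})

test_that("peak-center annotation follows the precedence rules", {
    g <- toy_genome(c(chr1 = 100000L))
    # gene A: +, body 20001-28000 (TSS0 20000); exon 22001-22400;
    # 5'UTR 20001-20100. gene B: TSS0 23000 (promoter window overlaps
    # gene A's exon region when widened)
    df <- data.frame(
        gene_id = c("gA", "gA", "gA", "gA", "gB"),
        chrom = "chr1", strand = c("+", "+", "+", "+", "+"),
        start = c(20000L, 22000L, 26000L, 27800L, 22900L),
        end = c(28000L, 22400L, 26400L, 28000L, 30000L),
        type = c("gene", "exon", "exon", "three_prime_utr", "gene"))
    models <- toy_models(df, g)
    mk_peak <- function(c0) GRanges("chr1", IRanges(c0 + 1, c0 + 1))
    ann <- function(c0) as.character(
        annotatePeakCenter(mk_peak(c0), models)$category)
    expect_equal(ann(20000), "promoter")      # center at TSS
    expect_equal(ann(50), "intergenic")       # far from everything
    expect_equal(ann(22200), "promoter")      # exon of A but promoter of B
    expect_equal(ann(25000), "intron")        # gene body, no exon
    expect_equal(ann(26200), "exon")
    expect_equal(ann(27900), "UTR")           # UTR beats the exon below it
    # exhaustive / mutually exclusive over a sweep of centers
    sweep <- annotatePeakCenter(GRanges("chr1",
                                        IRanges(seq(1, 99000, by = 237),
                                                width = 1)), models)
    expect_false(anyNA(sweep$category))
    expect_equal(sum(sweep$counts), length(seq(1, 99000, by = 237)))
})

test_that("peaks are assigned to the nearest TSS within range", {
    g <- toy_genome(c(chr1 = 1000000L))
    df <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                     strand = "+", start = c(100000L, 500000L),
                     end = c(105000L, 505000L), type = "gene")
    models <- toy_models(df, g)
    pk <- GRanges("chr1", IRanges(c(150001, 700001, 410001), width = 100))
    got <- assignPeakToGene(pk, models)
    expect_equal(got, c("g1", NA, "g2"))  # 50 kb; 195 kb none; 90 kb to g2
    # random toys vs exhaustive nearest-TSS oracle (incl. tie-break)
    set.seed(121)
    dfr <- data.frame(gene_id = sprintf("g%02d", 1:12), chrom = "chr1",
                      strand = "+",
                      start = sort(sample(seq(1e4, 9e5, by = 100), 12)),
                      end = 0L, type = "gene")
    dfr$end <- dfr$start + 3000L
    mr <- toy_models(dfr, g)
    pr <- GRanges("chr1", IRanges(sample(1:999000, 200), width = 150))
    c0 <- floor((start(pr) - 1 + end(pr)) / 2)
    expect_equal(assignPeakToGene(pr, mr),
                 oracle_assign(c0, rep("chr1", 200), dfr$start,
                               rep("chr1", 12), dfr$gene_id, 1e5))
})

test_that("partition percentages reproduce printed worked examples", {
    pct <- partitionSummary(c(intergenic = 1040, promoter = 192,
                              intron = 721, exon = 98, UTR = 35))
    expect_equal(unname(pct), c(49.86, 9.20, 34.56, 4.70, 1.68))
    expect_equal(sum(pct), 100, tolerance = 0.0003)
    expect_equal(unname(partitionSummary(c(overlap = 4042,
                                           non_overlap = 5827))[1]),
                 40.96)
    expect_equal(unname(partitionSummary(c(only = 7))), 100.00)
    expect_error(partitionSummary(c(a = 0, b = 0)), "positive")
    expect_error(partitionSummary(c(a = -1, b = 2)), "non-negative")
})

test_that("EED-region classification recovers planted archetypes", {
    set.seed(131)
    arch <- rbind(E1 = c(EED = 30, H3K27me3 = 5, H3K27ac = 30, HDAC2 = 30),
                  E2 = c(EED = 40, H3K27me3 = 10, H3K27ac = 40, HDAC2 = 15),
                  E3 = c(EED = 40, H3K27me3 = 40, H3K27ac = 5, HDAC2 = 10))
    truth <- sample(rep(c("E1", "E2", "E3"), times = c(40, 25, 25)))
    feats <- t(vapply(truth, function(k)
        arch[k, ] * exp(rnorm(4, 0, 0.15)), numeric(4)))
    colnames(feats) <- colnames(arch)
    got <- classifyEedRegions(feats, seed = 5)
    expect_gte(ari(got$class, truth), 0.9)
    # semantic labels follow ascending H3K27me3 centroids
    cm <- got$centroids[, "H3K27me3"]
    expect_true(cm[["E1"]] < cm[["E2"]] && cm[["E2"]] < cm[["E3"]])

    # invariance to row permutation
    perm <- sample(nrow(feats))
    got_p <- classifyEedRegions(feats[perm, ], seed = 5)
    expect_equal(as.character(got_p$class), as.character(got$class)[perm])
    # invariance to rescaling one feature column (post-standardization,
    # checked as identical assignments on separated archetypes)
    f2 <- feats
    f2[, "HDAC2"] <- f2[, "HDAC2"] * 37.5
    got_s <- classifyEedRegions(f2, seed = 5)
    expect_gte(ari(got_s$class, got$class), 0.99)

    expect_error(classifyEedRegions(feats[c(1, 1, 1), ], seed = 1),
                 "degenerate")
    expect_error(classifyEedRegions(feats[, 1:3]), "columns")
})
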