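test_that("bedGraph reading aggregates per-base values into bins", {
    g <- toy_genome(c(chr1 = 100L))
    f <- withr::local_tempfile(fileext = ".bedgraph")
    writeLines("chr1\t0\t100\t5", f)
    tr <- readBedGraph(f, g, binWidth = 100L)
    expect_equal(trackBins(tr)$chr1, 500)  # 5 per base over 100 bases

    # empty file -> all-zero track
    writeLines(character(0), f)
    tr0 <- readBedGraph(f, g, binWidth = 20L)
    expect_true(all(unlist(trackBins(tr0)) == 0))
    expect_equal(totalAligned(tr0), 0)

    # arbitrary sorted file equals per-base expansion oracle
    set.seed(11)
    len <- 10000L
    g2 <- toy_genome(c(chr1 = len))
    cuts <- sort(sample(0:len, 30))
    rec <- data.frame(start = head(cuts, -1), end = tail(cuts, -1),
                      value = sample(0:9, length(cuts) - 1, replace = TRUE))
    rec <- rec[rec$start < rec$end, ]
    f2 <- withr::local_tempfile(fileext = ".bedgraph")
    writeLines(sprintf("chr1\t%d\t%d\t%d", rec$start, rec$end, rec$value), f2)
    for (w in c(20L, 100L, 1000L)) {
        tr2 <- readBedGraph(f2, g2, binWidth = w)
        expect_equal(trackBins(tr2)$chr1, oracle_bin_sums(rec, len, w))
    }
})

test_that("bedGraph reading validates records and header total", {
    g <- toy_genome(c(chr1 = 200L))
    f <- withr::local_tempfile()
    writeLines(c("# total_aligned=12345", "chr1\t0\t100\t2"), f)
    expect_equal(totalAligned(readBedGraph(f, g, 20L)), 12345)
    writeLines("chr9\t0\t10\t1", f)
    expect_error(readBedGraph(f, g, 20L), "unknown chromosome")
    writeLines("chr1\t0\t300\t1", f)
    expect_error(readBedGraph(f, g, 20L), "bounds")
    writeLines(c("chr1\t0\t100\t1", "chr1\t50\t150\t1"), f)
    expect_error(readBedGraph(f, g, 20L), "non-overlapping")
})

test_that("bedGraph write/read round-trips a track", {
    set.seed(3)
    tr <- toy_track(list(chr1 = rpois(50, 4), chr2 = rpois(30, 4)))
    f <- withr::local_tempfile(fileext = ".bedgraph")
    writeBedGraph(tr, f)
    back <- readBedGraph(f, trackGenome(tr), binWidth(tr))
    expect_equal(trackBins(back), trackBins(tr))
    expect_equal(totalAligned(back), totalAligned(tr))
})

test_that("depth normalization scales per 10M reads and is idempotent", {
    tr <- toy_track(list(chr1 = c(10, 20, 30)), width = 100L, total = 1e7)
    expect_equal(trackBins(depthNormalize(tr)), trackBins(tr))
    tr2 <- toy_track(list(chr1 = c(10, 20, 30)), width = 100L, total = 2e7)
    expect_equal(trackBins(depthNormalize(tr2))$chr1, c(5, 10, 15))
    expect_equal(trackBins(depthNormalize(depthNormalize(tr2))),
                 trackBins(depthNormalize(tr2)))
    expect_error(depthNormalize(toy_track(list(chr1 = c(0, 0)), total = 0)),
                 "zero total")
})

test_that("input subtraction clips at zero and is monotone in chip", {
    chip <- toy_track(list(chr1 = c(5, 2, 7, 0)))
    input <- toy_track(list(chr1 = c(2, 5, 7, 1)))
    s <- subtractInput(chip, input)
    expect_equal(trackBins(s)$chr1, c(3, 0, 0, 0))
    expect_s4_class(s, "SignalTrack")

    set.seed(21)
    a <- rpois(200, 6); b <- rpois(200, 6)
    s1 <- subtractInput(toy_track(list(chr1 = a)), toy_track(list(chr1 = b)))
    expect_equal(trackBins(s1)$chr1, pmax(a - b, 0))  # elementwise oracle
    s2 <- subtractInput(toy_track(list(chr1 = a + 1)),
                        toy_track(list(chr1 = b)))
    expect_true(all(trackBins(s2)$chr1 >= trackBins(s1)$chr1))
    expect_true(all(unlist(trackBins(s1)) >= 0))
    expect_error(subtractInput(chip, toy_track(list(chr1 = rep(1, 8)),
                                               width = 10L)),
                 "bin width")
})

test_that("TSS window means match a brute-force per-base oracle", {
    set.seed(31)
    bins <- rpois(500, 5)  # 10 kb at 20 bp
    g <- toy_genome(c(chr1 = 10000L))
    sig <- toy_signal(list(chr1 = bins), genome = g)
    # genes with assorted TSS positions, including one clipped at the edge
    tss0 <- c(5000L, 4991L, 130L, 0L, 9990L)
    strands <- c("+", "-", "+", "+", "-")
    df <- data.frame(gene_id = paste0("g", 1:5), chrom = "chr1",
                     strand = strands,
                     start = ifelse(strands == "+", tss0, pmax(tss0 - 999, 0)),
                     end = ifelse(strands == "+", pmin(tss0 + 1000, 10000),
                                  tss0 + 1),
                     type = "gene")
    models <- toy_models(df, g)
    for (hw in c(500L, 1000L)) {
        got <- windowSignal(sig, models, hw)
        want <- vapply(tss0, oracle_window_mean, numeric(1),
                       bins = bins, bin_width = 20L, hw = hw)
        expect_equal(unname(got), want)
    }
    # constant signal maps every gene to that constant
    const <- toy_signal(list(chr1 = rep(3.5, 500)), genome = g)
    expect_true(all(windowSignal(const, models, 500L) == 3.5))
    # TSS at position 0: mean over the right half only
    expect_equal(unname(windowSignal(sig, models, 500L)["g4"]),
                 mean(bins[1:25]))
    expect_error(windowSignal(sig, models, 510L), "multiple")
})

test_that("genome-wide window distribution sums bins per window", {
    tr <- toy_track(list(chr1 = rep(2, 100), chr2 = rep(5, 50)))
    d <- genomeWindowDistribution(tr, window = 1000L)
    expect_equal(d, c(rep(100, 2), rep(250, 1)))
    # invariance of the multiset to chromosome order
    tr2 <- toy_track(list(chr2 = rep(5, 50), chr1 = rep(2, 100)))
    expect_equal(sort(genomeWindowDistribution(tr2, 1000L)), sort(d))
    set.seed(5)
    tr3 <- toy_track(list(chr1 = rpois(130, 3)))
    d3 <- genomeWindowDistribution(tr3, 500L)
    expect_equal(d3, as.numeric(tapply(trackBins(tr3)$chr1,
                                       (0:129) %/% 25, sum)))
    expect_equal(length(d3), 6)  # trailing partial window included
})

test_that("aggregate profiles are linear in anchors and strand-mirrored", {
    set.seed(41)
    bins <- rpois(500, 5)
    sig <- toy_signal(list(chr1 = bins))
    a1 <- data.frame(chrom = "chr1", pos = 3000, strand = "+")
    a2 <- data.frame(chrom = "chr1", pos = 6140, strand = "+")
    p1 <- aggregateProfile(sig, a1, 1000L)
    p2 <- aggregateProfile(sig, a2, 1000L)
    p12 <- aggregateProfile(sig, rbind(a1, a2), 1000L)
    expect_equal(p12, (p1 + p2) / 2)
    expect_length(p1, 100)

    # constant signal -> flat profile
    flat <- aggregateProfile(toy_signal(list(chr1 = rep(2, 500))), a1, 500L)
    expect_true(all(flat == 2))

    # minus-strand profile is the mirror of the plus-strand profile
    am <- transform(a1, strand = "-")
    expect_equal(unname(aggregateProfile(sig, am, 1000L)),
                 unname(rev(p1)))

    expect_error(aggregateProfile(sig, a1[0, ], 1000L), "empty anchor")
    expect_error(aggregateProfile(sig, data.frame(chrom = "chr1", pos = 10,
                                                  strand = "+"), 1000L),
                 "beyond")
})

test_that("proximal/distal labels match exhaustive intersection", {
    g <- toy_genome(c(chr1 = 500000L))
    df <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                     strand = c("+", "-"),
                     start = c(100001L, 300001L), end = c(105000L, 305000L),
                     type = "gene")
    models <- toy_models(df, g)  # TSS0: 100000 (+), 304999 (-)
    peaks <- GRanges("chr1", IRanges(c(100001, 401000, 96000, 310100),
                                     width = c(200, 500, 100, 1000)))
    lab <- proximalDistalSplit(peaks, models)
    expect_equal(as.character(lab),
                 c("proximal", "distal", "proximal", "distal"))
    # random toy vs exhaustive oracle against the +-5 kb TSS windows
    set.seed(51)
    rnd <- GRanges("chr1", IRanges(sample(1:490000, 50), width = 300))
    tssw <- GRanges("chr1", IRanges(c(100000, 304999) + 1 - 5000,
                                    width = 10001))
    expect_equal(proximalDistalSplit(rnd, models) == "proximal",
                 setNames(oracle_overlaps_any(rnd, tssw), NULL))
})
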