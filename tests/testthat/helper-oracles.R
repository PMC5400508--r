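# Shared fixtures and independent brute-force oracles. Oracles here are
# deliberately written as naive per-base / exhaustive computations so
# that they stay independent of the vectorized implementation paths.

library(GenomicRanges)

toy_genome <- function(lengths = c(chr1 = 2000L)) {
    GenomeInfoDb::Seqinfo(seqnames = names(lengths),
                          seqlengths = unname(lengths))
}

toy_track <- function(bins, width = 20L, genome = NULL, total = NULL) {
    if (is.null(genome))
        genome <- toy_genome(setNames(
            as.integer(vapply(bins, length, integer(1)) * width),
            names(bins)))
    CoverageTrack(lapply(bins, as.numeric), width, genome, total)
}

toy_signal <- function(bins, width = 20L, genome = NULL) {
    if (is.null(genome))
        genome <- toy_genome(setNames(
            as.integer(vapply(bins, length, integer(1)) * width),
            names(bins)))
    SignalTrack(lapply(bins, as.numeric), width, genome)
}

# one-gene models builder; tss0 is the 0-based TSS base position
toy_models <- function(df, genome) {
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                  strand = df$strand, seqinfo = genome)
    S4Vectors::mcols(gr)$gene_id <- df$gene_id
    S4Vectors::mcols(gr)$type <- df$type
    new("GeneModels", features = gr)
}

# Per-base expansion of a bedGraph-like record table, then per-bin sums.
oracle_bin_sums <- function(records, chrom_len, bin_width) {
    base <- numeric(chrom_len)
    for (i in seq_len(nrow(records)))
        base[(records$start[i] + 1):records$end[i]] <- records$value[i]
    vapply(seq_len(ceiling(chrom_len / bin_width)), function(b) {
        lo <- (b - 1) * bin_width + 1
        hi <- min(b * bin_width, chrom_len)
        sum(base[lo:hi])
    }, numeric(1))
}

# Naive mean of per-bin values overlapping [p - hw, p + hw), 0-based p.
oracle_window_mean <- function(bins, bin_width, p, hw) {
    keep <- vapply(seq_along(bins), function(b) {
        lo0 <- (b - 1) * bin_width
        hi0 <- b * bin_width
        lo0 < p + hw && hi0 > p - hw
    }, logical(1))
    mean(bins[keep])
}

# Exhaustive pairwise interval intersection (0-based half-open inputs
# given as 1-based GRanges).
oracle_overlaps_any <- function(a, b) {
    vapply(seq_along(a), function(i) {
        any(as.character(seqnames(b)) == as.character(seqnames(a))[i] &
            start(b) <= end(a)[i] & end(b) >= start(a)[i])
    }, logical(1))
}

# Exhaustive nearest-TSS assignment with lexicographic tie-break.
oracle_assign <- function(centers0, center_chrom, tss0, tss_chrom, gene_id,
                          max_dist) {
    vapply(seq_along(centers0), function(i) {
        d <- ifelse(tss_chrom == center_chrom[i],
                    abs(tss0 - centers0[i]), Inf)
        ok <- which(d <= max_dist)
        if (!length(ok)) return(NA_character_)
        ok <- ok[order(d[ok], gene_id[ok])]
        gene_id[ok[1]]
    }, character(1))
}

# Exact two-sided rank-sum p by enumerating Mann-Whitney U over all
# subsets (independent statistic route: counts of x>y pairs with ties
# as 1/2).
oracle_ranksum_p <- function(x, y) {
    n <- length(x); m <- length(y); N <- n + m
    pool <- c(x, y)
    u_of <- function(idx) {
        xs <- pool[idx]; ys <- pool[-idx]
        sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    }
    obs <- u_of(seq_len(n))
    mu <- n * m / 2
    us <- combn(N, n, u_of)
    mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

small_config <- function(seed = 1L, ...) {
    simulationConfig(seed = seed, nChroms = 2L, chromLength = 1.5e6,
                     nGenes = 120L, nEedRegions = 36L, ...)
}

make_signal <- function(truth, mark, condition, seed) {
    pr <- simulateChipCoverage(truth, mark, condition, seed = seed)
    subtractInput(depthNormalize(pr$chip), depthNormalize(pr$input))
}

sim_counts <- function(n_genes, n_per_group, mu, disp, lfc = 0, seed = 1) {
    withr::with_seed(seed, {
        base <- rlnorm(n_genes, log(mu), 0.5)
        lfc <- rep(lfc, length.out = n_genes)
        m <- cbind(matrix(rep(base, n_per_group), ncol = n_per_group),
                   matrix(rep(base * 2^lfc, n_per_group),
                          ncol = n_per_group))
        cnt <- matrix(rnbinom(length(m), mu = as.vector(m), size = 1 / disp),
                      nrow = n_genes,
                      dimnames = list(paste0("g", seq_len(n_genes)),
                                      c(paste0("A", seq_len(n_per_group)),
                                        paste0("B", seq_len(n_per_group)))))
        cnt
    })
}
de_groups <- function(k) factor(rep(c("A", "B"), each = k),
                                levels = c("A", "B"))

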