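## Differential expression, gene-class clustering, quartile
## stratification, rescue assessment, and the rank-sum test.

#' Negative-binomial differential expression between two groups
#'
#' A compact, fully specified two-group NB test: library sizes by
#' median-of-ratios; per-gene dispersion by the method of moments,
#' shrunk toward a fitted mean-dispersion trend `a0 + a1 / mu`
#' (prior weight `d0 = 10` residual-df equivalents); a Wald test on the
#' log2 fold change; BH adjustment; and the status rule
#' up iff FC > 1.5 and adjusted p < 0.05, down iff FC < 0.67 and
#' adjusted p < 0.05.
#'
#' @param counts integer matrix, genes x samples, with rownames.
#' @param groups factor (or character) over samples with exactly two
#'   levels; fold changes are second level over first.
#' @param fcUp,fcDown fold-change thresholds (defaults 1.5 and 0.67).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return data.frame with gene, baseMean, log2FC, pvalue, padj, status
#' @export
callDifferentialGenes <- function(counts, groups, fcUp = 1.5, fcDown = 0.67,
                                  alpha = 0.05) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
    groups <- factor(groups)
    if (nlevels(groups) != 2)
        stop2("groups must have exactly two levels")
    if (any(table(groups) < 2))
        stop2("each group needs at least 2 replicates")
    if (any(counts < 0) || any(counts != floor(counts)))
        stop2("counts must be non-negative integers")

    zero <- rowSums(counts) == 0
    if (any(zero)) {
        message("dropping ", sum(zero), " all-zero gene row(s)")
        counts <- counts[!zero, , drop = FALSE]
    }

    # median-of-ratios size factors
    logg <- rowMeans(log(counts + 0L))
    use <- is.finite(logg)
    sf <- if (any(use)) {
        apply(counts, 2, function(cnt)
            exp(median((log(cnt) - logg)[use & cnt > 0])))
    } else {
        cs <- colSums(counts)
        cs / exp(mean(log(cs)))
    }
    sf <- sf / exp(mean(log(sf)))
    q <- sweep(counts, 2, sf, "/")

    i1 <- groups == levels(groups)[1]
    i2 <- !i1
    n1 <- sum(i1); n2 <- sum(i2)
    m1 <- rowMeans(q[, i1, drop = FALSE])
    m2 <- rowMeans(q[, i2, drop = FALSE])
    v1 <- apply(q[, i1, drop = FALSE], 1, var)
    v2 <- apply(q[, i2, drop = FALSE], 1, var)
    baseMean <- rowMeans(q)

    # moment dispersion: Var = mu + alpha mu^2, pooled across groups
    num <- (n1 - 1) * (v1 - m1) + (n2 - 1) * (v2 - m2)
    den <- (n1 - 1) * m1^2 + (n2 - 1) * m2^2
    a_mom <- pmax(num / pmax(den, 1e-12), 1e-8)

    # mean-dispersion trend a0 + a1/mu via decile-binned medians
    ok <- baseMean > 0
    a_tr <- rep(1e-8, length(a_mom))
    if (sum(ok) >= 10) {
        br <- unique(quantile(baseMean[ok], probs = seq(0, 1, 0.1)))
        bin <- cut(baseMean[ok], breaks = br, include.lowest = TRUE)
        med_a <- tapply(a_mom[ok], bin, median)
        med_m <- tapply(baseMean[ok], bin, median)
        keep <- is.finite(med_a) & is.finite(med_m)
        if (sum(keep) >= 2) {
            fit <- lm(med_a[keep] ~ I(1 / med_m[keep]))
            a0 <- max(coef(fit)[1], 0)
            a1 <- max(coef(fit)[2], 0)
            a_tr <- pmax(a0 + a1 / pmax(baseMean, 1e-8), 1e-8)
        } else {
            a_tr <- rep(max(median(a_mom[ok]), 1e-8), length(a_mom))
        }
    }
    d_g <- n1 + n2 - 2
    d0 <- 10
    alpha_use <- (d_g * a_mom + d0 * a_tr) / (d_g + d0)

    lfc <- log2((m2 + 0.5) / (m1 + 0.5))
    vlog2 <- function(m, n) (m + 0.5 + alpha_use * (m + 0.5)^2) /
        (n * (m + 0.5)^2 * log(2)^2)
    se <- sqrt(vlog2(m1, n1) + vlog2(m2, n2))
    z <- lfc / se
    pval <- 2 * pnorm(-abs(z))
    padj <- p.adjust(pval, method = "BH")
    fc <- 2^lfc
    status <- ifelse(fc > fcUp & padj < alpha, "up",
              ifelse(fc < fcDown & padj < alpha, "down", "unchanged"))
    data.frame(gene = rownames(counts), baseMean = baseMean, log2FC = lfc,
               pvalue = pval, padj = padj,
               status = factor(status, levels = c("up", "down", "unchanged")),
               row.names = NULL)
}

#' Cluster upregulated genes into C1-C3 by promoter mark dynamics
#'
#' k-means (k = 3) on log1p-transformed, column-standardized TSS signals
#' for WT H3K27me3, KO H3K27me3 and WT EED. Clusters are relabeled
#' semantically: C2 is the cluster with the lowest mean WT H3K27me3
#' (mark low); of the remaining two, C1 has the larger mean WT-to-KO
#' H3K27me3 drop (mark lost) and C3 the smaller (mark retained).
#'
#' @param upGenes character vector of upregulated gene ids.
#' @param wtMe3,koMe3,wtEed named per-gene TSS signals covering `upGenes`.
#' @param seed deterministic seed.
#' @return list with `class` (named factor C1/C2/C3) and `centroids`
#'   (mean raw feature per class)
#' @export
clusterUpregulatedGenes <- function(upGenes, wtMe3, koMe3, wtEed, seed = 1L) {
    if (length(upGenes) < 3)
        stop2("need at least 3 upregulated genes")
    if (!all(upGenes %in% names(wtMe3)) || !all(upGenes %in% names(koMe3)) ||
        !all(upGenes %in% names(wtEed)))
        stop2("all upregulated genes need all three features")
    F <- cbind(wt_me3 = wtMe3[upGenes], ko_me3 = koMe3[upGenes],
               wt_eed = wtEed[upGenes])
    fit <- .kmeans_classify(F, 3L, seed)
    wt_mean <- tapply(F[, "wt_me3"], fit$cluster, mean)
    drop_mean <- tapply(F[, "wt_me3"] - F[, "ko_me3"], fit$cluster, mean)
    # if no cluster loses an appreciable fraction of its WT mark, the
    # C1 (lost) vs C3 (retained) distinction is arbitrary
    if (max(drop_mean) < 0.25 * max(wt_mean))
        warning("low separation: no cluster shows an appreciable ",
                "H3K27me3 drop; C1/C3 labels are arbitrary")
    c2 <- names(which.min(wt_mean))
    rest <- setdiff(names(wt_mean), c2)
    c1 <- rest[which.max(drop_mean[rest])]
    c3 <- setdiff(rest, c1)
    relabel <- setNames(c("C1", "C2", "C3"), c(c1, c2, c3))
    cls <- setNames(factor(relabel[as.character(fit$cluster)],
                           levels = c("C1", "C2", "C3")), upGenes)
    cent <- do.call(rbind, lapply(split(as.data.frame(F), cls), colMeans))
    list(class = cls, centroids = cent)
}

#' Stratify genes by WT signal quartiles and compare conditions
#'
#' Genes are split into four near-equal quartiles of WT signal (by rank;
#' sizes differ by at most one), and within each quartile WT and KO
#' signals are compared by the two-sided rank-sum test.
#'
#' @param wt,ko named per-gene signals over the same universe.
#' @return data.frame with quartile, n, median_wt, median_ko, p
#' @export
stratifyByWtQuartiles <- function(wt, ko) {
    if (!identical(sort(names(wt)), sort(names(ko))))
        stop2("wt and ko must cover the same gene universe")
    n <- length(wt)
    if (n < 8) stop2("need at least 8 genes to form quartiles")
    ko <- ko[names(wt)]
    r <- rank(wt, ties.method = "first")
    quart <- ceiling(4 * r / n)
    if (length(unique(quart)) < 4)
        stop2("ties collapsed a quartile; tie report: ",
              paste(capture_ties(wt), collapse = ", "))
    do.call(rbind, lapply(1:4, function(qi) {
        sel <- quart == qi
        data.frame(quartile = paste0("Q", qi), n = sum(sel),
                   median_wt = median(wt[sel]), median_ko = median(ko[sel]),
                   p = rankSumTest(wt[sel], ko[sel])$p.value)
    }))
}

capture_ties <- function(x) {
    t <- table(x)
    names(t)[t > 1]
}

#' Bin genes by a rescue signal ratio
#'
#' With pseudocount `eps`, the ratio `r = (a + eps) / (b + eps)` is
#' binned into `r >= 1.5` (strongly reduced by rescue), `1 < r < 1.5`
#' (mildly reduced) and `r <= 1` (not changed); the bins partition the
#' gene set.
#'
#' @param a,b named per-gene TSS signals (e.g. H3K27ac in CKO-luc vs
#'   CKO-HDAC1/2) over the same universe.
#' @param eps pseudocount; defaults to the 1st percentile of positive
#'   pooled signal.
#' @return list with `ratio`, `bin` (factor) and `counts`
#' @export
rescueRatioBins <- function(a, b, eps = NULL) {
    if (!identical(sort(names(a)), sort(names(b))))
        stop2("a and b must cover the same gene universe")
    b <- b[names(a)]
    if (any(a < 0) || any(b < 0)) stop2("negative signals")
    if (is.null(eps)) {
        pos <- c(a, b)[c(a, b) > 0]
        eps <- if (length(pos)) unname(quantile(pos, 0.01)) else 1e-6
    }
    if (eps <= 0) stop2("eps must be positive")
    r <- (a + eps) / (b + eps)
    bin <- ifelse(r >= 1.5, "ge1.5", ifelse(r > 1, "1to1.5", "le1"))
    bin <- setNames(factor(bin, levels = c("ge1.5", "1to1.5", "le1")),
                    names(a))
    list(ratio = r, bin = bin, counts = table(bin))
}

#' Paired change ratios with rank correlation
#'
#' Pairs each gene's log2 signal ratio under loss of function with its
#' log2 ratio under rescue and reports the Spearman correlation -- the
#' substrate of rescue scatterplots.
#'
#' @param deltaLof,deltaRescue named positive per-gene ratios over the
#'   same universe.
#' @return list with `table` (gene, log2_lof, log2_rescue) and `rho`
#' @export
rescueChangeScatter <- function(deltaLof, deltaRescue) {
    if (!identical(sort(names(deltaLof)), sort(names(deltaRescue))))
        stop2("shared gene universe required")
    deltaRescue <- deltaRescue[names(deltaLof)]
    if (length(deltaLof) < 3) stop2("need at least 3 genes")
    tab <- data.frame(gene = names(deltaLof),
                      log2_lof = log2(deltaLof),
                      log2_rescue = log2(deltaRescue), row.names = NULL)
    list(table = tab,
         rho = cor(tab$log2_lof, tab$log2_rescue, method = "spearman"))
}

#' Two-sided Wilcoxon-Mann-Whitney rank-sum test
#'
#' For samples with at most 10 observations each, the exact two-sided
#' p-value is computed by full enumeration of all `C(n+m, n)` group
#' assignments of the (tie-averaged) ranks:
#' `p = P(|W - E W| >= |w_obs - E W|)`. Larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `p.value`, `statistic` (rank sum of `x`) and
#'   `method`
#' @export
rankSumTest <- function(x, y) {
    if (!length(x) || !length(y)) stop2("empty sample")
    n <- length(x); m <- length(y); N <- n + m
    rk <- rank(c(x, y))
    W <- sum(rk[seq_len(n)])
    mu <- n * (N + 1) / 2
    if (n <= 10 && m <= 10) {
        sums <- combn(N, n, function(i) sum(rk[i]))
        p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
        return(list(p.value = p, statistic = W, method = "exact enumeration"))
    }
    ties <- table(rk)
    sig2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    list(p.value = min(1, 2 * pnorm(-abs(z))), statistic = W,
         method = "normal approximation with tie correction")
}
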