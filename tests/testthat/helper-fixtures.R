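## shared fixtures and independent oracles (kept deliberately naive)

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Matrix)
})

## ContactMatrix from a dense symmetric matrix, bins of `res` bp on one or
## more chromosomes
toyContactMatrix <- function(mat, res = 100, chrom = "chrT",
                             normalized = FALSE) {
    n <- nrow(mat)
    sizes <- stats::setNames(n * res, chrom)
    bins <- binsFromSizes(sizes, res)
    HiCdci:::newContactMatrix(bins, Matrix(mat, sparse = TRUE),
                              normalized = normalized)
}

## random sparse symmetric count matrix
randomCounts <- function(n, density = 0.2, seed = 1) {
    withr::with_seed(seed, {
        m <- matrix(0, n, n)
        ut <- which(upper.tri(m, diag = TRUE))
        pick <- sample(ut, ceiling(length(ut) * density))
        m[pick] <- rpois(length(pick), 20)
        m + t(m) - diag(diag(m))
    })
}

## O(n*m) exhaustive nearest-gap-distance scan on 0-based coordinates
bruteNearest <- function(loci, regions) {
    lch <- as.character(seqnames(loci))
    rch <- as.character(seqnames(regions))
    vapply(seq_along(loci), function(i) {
        best <- Inf
        for (j in seq_along(regions)) {
            if (rch[j] != lch[i]) next
            ls <- start(loci)[i] - 1; le <- end(loci)[i]
            rs <- start(regions)[j] - 1; re <- end(regions)[j]
            d <- max(rs - le, ls - re, 0)
            if (d < best) best <- d
        }
        best
    }, numeric(1))
}

## exact two-sided Mann-Whitney p by enumerating all group assignments
bruteMannWhitneyP <- function(x, y) {
    pooled <- c(x, y)
    n1 <- length(x); n <- length(pooled)
    uStat <- function(idx) {
        xx <- pooled[idx]; yy <- pooled[-idx]
        sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
    }
    obs <- uStat(seq_len(n1))
    mid <- n1 * (n - n1) / 2
    combs <- utils::combn(n, n1)
    us <- apply(combs, 2, uStat)
    mean(abs(us - mid) >= abs(obs - mid) - 1e-9)
}

## Spearman rho via explicit rank arithmetic (counting, no rank())
bruteSpearman <- function(x, y) {
    manualRank <- function(v) {
        vapply(v, function(a) sum(v < a) + (1 + sum(v == a)) / 2, numeric(1))
    }
    rx <- manualRank(x); ry <- manualRank(y)
    mx <- mean(rx); my <- mean(ry)
    sum((rx - mx) * (ry - my)) /
        sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

## boundary F1 of a called TADSet against the planted truth
plantedF1 <- function(called, truth, resolution = 1e5, tolBins = 1) {
    unname(boundaryStats(called, truth, resolution, tolBins)["f1"])
}
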