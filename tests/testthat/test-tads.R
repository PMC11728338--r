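## a normalized two-block toy: strong within-block, weak cross-block contact
blockMatrix <- function(n = 20, split = 10, hi = 8, lo = 1) {
    lab <- rep(1:2, c(split, n - split))
    mat <- ifelse(outer(lab, lab, "=="), hi, lo)
    diag(mat) <- hi
    mat
}

test_that("features are banded log1p observed/expected values", {
    mat <- randomCounts(10, density = 0.8, seed = 4) + 1
    m <- toyContactMatrix(mat, normalized = TRUE)
    w <- 3
    feat <- extractFeatures(m, "chrT", windowBins = w)
    ## direct per-diagonal expectation, by loops
    n <- nrow(mat)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        d <- abs(i - j)
        if (d > w) {
            expect_identical(feat[i, j], 0)
        } else {
            diagVals <- mat[cbind(seq_len(n - d), seq_len(n - d) + d)]
            expect_equal(feat[i, j], log1p(mat[i, j] / mean(diagVals)))
        }
    }
    expect_error(extractFeatures(toyContactMatrix(mat), "chrT"),
                 "normalized")
    expect_error(extractFeatures(m, "chrMissing"), "not present")
})

test_that("clustering separates a noiseless two-block matrix exactly", {
    m <- toyContactMatrix(blockMatrix(), normalized = TRUE)
    ts <- segmentByClustering(m, "chrT", k = 2, windowBins = 5)
    expect_length(tads(ts), 2)
    expect_equal(end(tads(ts))[1], 10 * 100)
    ## determinism: same input and seed give the identical segmentation
    ts2 <- segmentByClustering(m, "chrT", k = 2, windowBins = 5)
    expect_identical(start(tads(ts)), start(tads(ts2)))
    expect_error(segmentByClustering(m, "chrT", k = 1), "out of range")
    expect_error(segmentByClustering(m, "chrT", k = 11), "out of range")
})

test_that("partition quality matches a double-loop recomputation", {
    mat <- randomCounts(20, density = 0.9, seed = 5) + 2
    m <- toyContactMatrix(mat, normalized = TRUE)
    ts <- segmentByClustering(m, "chrT", k = 3, windowBins = 5)
    q <- tadQuality(m, ts)
    ## brute force on the same O/E definition
    n <- nrow(mat)
    oe <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
        d <- abs(i - j)
        diagVals <- mat[cbind(seq_len(n - d), seq_len(n - d) + d)]
        oe[i, j] <- mat[i, j] / mean(diagVals)
    }
    ends <- end(tads(ts)) / 100
    lab <- rep(seq_along(ends), diff(c(0, ends)))
    maxSize <- max(diff(c(0, ends)))
    intra <- c(); inter <- c()
    for (i in 1:n) for (j in 1:n) {
        d <- abs(i - j)
        if (d == 0) next
        if (lab[i] == lab[j]) intra <- c(intra, oe[i, j])
        else if (d <= maxSize) inter <- c(inter, oe[i, j])
    }
    expect_equal(q, mean(intra) - mean(inter))
})

test_that("quality is discriminative and vanishes on uniform matrices", {
    m <- toyContactMatrix(blockMatrix(), normalized = TRUE)
    mkset <- function(split) {
        gr <- GRanges("chrT", IRanges(c(1, split * 100 + 1),
                                      c(split * 100, 2000)))
        mcols(gr)$quality <- NA_real_
        new("TADSet", chrom = "chrT", tads = gr, kSelected = 2L,
            quality = NA_real_, seed = 0L)
    }
    expect_gt(tadQuality(m, mkset(10)), tadQuality(m, mkset(6)))
    uni <- toyContactMatrix(matrix(5, 20, 20), normalized = TRUE)
    expect_equal(tadQuality(uni, mkset(10)), 0)
    expect_equal(tadQuality(uni, mkset(5)), 0)
    expect_error(tadQuality(m, new("TADSet", chrom = "chrT",
                                   tads = GRanges(), kSelected = 1L,
                                   quality = NA_real_, seed = 0L)),
                 "empty")
})

test_that("best-k selection recovers a planted partition", {
    cfg <- simulationConfig(chromLengths = c(chrS1 = 3e7),
                            tadSizeRange = c(25, 50), tadEnrichment = 2)
    sm <- simulateMatrix(cfg, seed = 5)
    mN <- iceNormalize(sm$matrix)
    ts <- callBestTads(mN)$chrS1
    bs <- boundaryStats(ts, sm$truth$tads$chrS1, 1e5, tolBins = 1)
    expect_gte(bs["precision"], 0.8)
    expect_gte(bs["recall"], 0.8)
    ## partition validity: tiles the chromosome without overlap, bin-aligned
    g <- tads(ts)
    expect_equal(start(g)[1], 1)
    expect_equal(end(g)[length(g)], 3e7)
    if (length(g) > 1)
        expect_true(all(start(g)[-1] == end(g)[-length(g)] + 1))
    expect_true(all((start(g) - 1) %% 1e5 == 0))
    ## quality optimality over re-generated candidates
    for (k in c(4, 8, 12)) {
        cand <- segmentByClustering(mN, "chrS1", k)
        expect_gte(ts@quality, tadQuality(mN, cand))
    }
})

test_that("structureless chromosomes come back as a single spanning domain", {
    cfg <- simulationConfig(chromLengths = c(chrS1 = 3e7),
                            tadSizeRange = c(300, 300))
    mN <- iceNormalize(simulateMatrix(cfg, seed = 2)$matrix)
    ts <- callBestTads(mN)$chrS1
    expect_length(tads(ts), 1)
    expect_equal(ts@kSelected, 1L)
})

test_that("equal-quality candidates resolve to the smaller k", {
    ## uniform matrix: every partition scores exactly 0, baseline k = 1 wins
    uni <- toyContactMatrix(matrix(4, 30, 30), normalized = TRUE)
    ts <- callBestTads(uni, kRange = 2:5)$chrT
    expect_equal(ts@kSelected, 1L)
    expect_equal(ts@quality, 0)
})

test_that("TAD calls export as BED6 plus a boundary table", {
    cfg <- simulationConfig(chromLengths = c(chrS1 = 5e6))
    mN <- iceNormalize(simulateMatrix(cfg, seed = 3)$matrix)
    ts <- callBestTads(mN)
    d <- withr::local_tempdir()
    writeTadBed(ts, file.path(d, "t.bed"), file.path(d, "b.tsv"))
    bed <- read.table(file.path(d, "t.bed"), sep = "\t")
    expect_equal(ncol(bed), 6)
    expect_true(all(bed$V2 < bed$V3))
    b <- read.delim(file.path(d, "b.tsv"))
    expect_true(all(b$boundary %in% boundaries(ts$chrS1)))
})
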