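test_that("without TAD enrichment expected counts depend only on separation", {
    cfg <- simulationConfig(chromLengths = c(chrS1 = 3e6),
                            tadEnrichment = 0, decayExponent = 1,
                            baseIntensity = 100, noise = "none")
    m <- as.matrix(contacts(simulateMatrix(cfg, seed = 1)$matrix))
    n <- nrow(m)
    for (d in c(1, 5, 10)) {
        vals <- m[cbind(seq_len(n - d), seq_len(n - d) + d)]
        expect_equal(max(vals) - min(vals), 0)
        expect_equal(vals[1], 100 * (1 + d)^-1)
    }
    ## decay: expected counts non-increasing in separation
    diagMeans <- sapply(0:20, function(d)
        mean(m[cbind(seq_len(n - d), seq_len(n - d) + d)]))
    expect_true(all(diff(diagMeans) <= 0))
})

test_that("the generator is deterministic given (config, seed)", {
    cfg <- simulationConfig(chromLengths = c(chrS1 = 5e6))
    a <- simulateMatrix(cfg, seed = 11)
    b <- simulateMatrix(cfg, seed = 11)
    expect_identical(as.matrix(contacts(a$matrix)),
                     as.matrix(contacts(b$matrix)))
    expect_identical(start(tads(a$truth$tads$chrS1)),
                     start(tads(b$truth$tads$chrS1)))
    c <- simulateMatrix(cfg, seed = 12)
    expect_false(all(contacts(a$matrix) == contacts(c$matrix)))
})

test_that("planted TADs elevate intra-domain counts at matched separation", {
    cfg <- simulationConfig(chromLengths = c(chrS1 = 3e7),
                            tadEnrichment = 1.5)
    sm <- simulateMatrix(cfg, seed = 11)
    m <- as.matrix(contacts(sm$matrix))
    lab <- HiCdci:::truthLabels(cfg, sm$truth)$chrS1
    for (d in 1:4) {
        i <- seq_len(length(lab) - d)
        same <- lab[i] == lab[i + d]
        vals <- m[cbind(i, i + d)]
        expect_gt(mean(vals[same]), mean(vals[!same]))
    }
})

test_that("condition pairs plant directional differences where specified", {
    spec <- data.frame(chrom = "chrS1", startBin = 20, endBin = 24, fold = 2)
    cfg <- simulationConfig(chromLengths = c(chrS1 = 1e7), dciSpec = spec)
    pr <- simulateConditionPair(cfg, seed = 13)
    A <- as.matrix(contacts(pr$matrixA))
    B <- as.matrix(contacts(pr$matrixB))
    w <- 20:24
    expect_gt(mean(B[w, w] - A[w, w]), 0)
    ## outside the window the two conditions are exchangeable in expectation
    out <- 40:80
    expect_lt(abs(mean(B[out, out] - A[out, out])),
              2 * sd(B[out, out] - A[out, out]) / length(out))
    expect_equal(as.character(seqnames(pr$truth$dcis)), "chrS1")

    bad <- simulationConfig(chromLengths = c(chrS1 = 1e7),
                            dciSpec = data.frame(chrom = "chrS1",
                                                 startBin = 99, endBin = 110,
                                                 fold = 2))
    expect_error(simulateConditionPair(bad, seed = 1), "outside")
    over <- simulationConfig(chromLengths = c(chrS1 = 1e7),
                             dciSpec = data.frame(chrom = "chrS1",
                                                  startBin = c(5, 8),
                                                  endBin = c(9, 12),
                                                  fold = 2))
    expect_error(simulateConditionPair(over, seed = 1), "overlapping")
})

test_that("a chromosome shorter than the minimum TAD errors", {
    cfg <- simulationConfig(chromLengths = c(tiny = 3e5),
                            tadSizeRange = c(6, 15))
    expect_error(simulateMatrix(cfg, seed = 1), "shorter than")
})

test_that("inverse-mode loci anticorrelate expression with distance", {
    cfg <- simulationConfig(nLoci = 60)
    cfg$dciSpec <- randomDciSpec(cfg, n = 6, seed = 3)
    regions <- dciSpecRegions(cfg)
    loci <- simulateExpressedLoci(cfg, truth = list(dcis = regions),
                                  seed = 5)
    d <- mcols(nearestDistance(loci, regions))$distance
    expect_lt(cor(rank(mcols(loci)$normalized_count), rank(d)), 0)
})

test_that("independent-mode sample Spearman coefficients centre at zero", {
    cfg <- simulationConfig(locusEffect = "independent")
    cfg$dciSpec <- randomDciSpec(cfg, n = 10, seed = 17)
    regions <- dciSpecRegions(cfg)
    rhos <- vapply(1:500, function(i) {
        loci <- simulateExpressedLoci(cfg, seed = 17000 + i)
        d <- mcols(nearestDistance(loci, regions))$distance
        spearmanAssoc(mcols(loci)$normalized_count, d)$rho
    }, numeric(1))
    expect_lt(abs(mean(rhos)), 0.05)
})

test_that("the locus generator yields the configured cardinality and ranks", {
    cfg <- simulationConfig(nLoci = 19, locusEffect = "independent")
    loci <- simulateExpressedLoci(cfg, seed = 2)
    expect_length(loci, 19)
    expect_true(all(mcols(loci)$expression_rank %in% 1:4))
    expect_setequal(unique(mcols(loci)$expression_rank), 1:4)
    cfgBad <- simulationConfig(nLoci = 2)
    expect_error(simulateExpressedLoci(cfgBad, seed = 1), "at least 3")
})
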