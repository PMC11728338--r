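lociGR <- function(chrom, s0, e0, counts = NULL) {
    g <- GRanges(chrom, IRanges(s0 + 1, e0))
    mcols(g)$name <- sprintf("locus%02d", seq_along(g))
    if (is.null(counts)) counts <- rev(seq_along(g)) * 10
    mcols(g)$normalized_count <- counts
    mcols(g)$expression_rank <- expressionRanks(counts)
    g
}

test_that("gap distances follow interval arithmetic", {
    loci <- lociGR("chr1", c(300, 120), c(310, 160))
    regions <- GRanges("chr1", IRanges(101, 200))
    ld <- nearestDistance(loci, regions)
    expect_equal(mcols(ld)$distance, c(100, 0))
    ## touching intervals have distance 0
    lociT <- lociGR("chr1", 200, 250)
    expect_equal(mcols(nearestDistance(lociT, regions))$distance, 0)
    ## locus without a same-chromosome region errors by name
    lociX <- lociGR("chrX", 10, 20)
    expect_error(nearestDistance(lociX, regions), "locus01")
    expect_error(nearestDistance(loci, GRanges()), "non-empty")
})

test_that("nearest distances equal the exhaustive scan on random fixtures", {
    set <- withr::with_seed(6, {
        lchr <- sample(c("c1", "c2"), 100, replace = TRUE)
        ls <- sample.int(1e6, 100)
        rchr <- sample(c("c1", "c2"), 50, replace = TRUE)
        rs <- sample.int(1e6, 50)
        list(loci = lociGR(lchr, ls, ls + 500),
             regions = GRanges(rchr, IRanges(rs + 1, rs + 2000)))
    })
    ld <- nearestDistance(set$loci, set$regions)
    expect_equal(mcols(ld)$distance, bruteNearest(set$loci, set$regions))
    ## ties break toward the leftmost region
    loci <- lociGR("c1", 500, 600)
    regions <- GRanges("c1", IRanges(c(401, 301, 651), c(450, 350, 700)))
    ld2 <- nearestDistance(loci, regions)
    expect_equal(mcols(ld2)$distance, 50)
    expect_equal(mcols(ld2)$nearest_region, 1L)  # leftmost of the two at 50
})

test_that("Spearman association reproduces known values", {
    ## perfect monotone decrease
    expect_equal(spearmanAssoc(1:5, c(10, 8, 6, 4, 2))$rho, -1)
    ## tie handling equals the explicit rank-arithmetic computation
    x <- c(3, 1, 4, 1, 5, 9, 2, 6)
    y <- c(2, 7, 1, 8, 2, 8, 1, 8)
    expect_equal(spearmanAssoc(x, y)$rho, bruteSpearman(x, y))
    expect_error(spearmanAssoc(1:3, 3:1), "at least 4")
    expect_error(spearmanAssoc(rep(1, 5), 1:5), "zero variance")
})

test_that("permutation p saturates when regions tile the genome", {
    sizes <- c(c1 = 1e5, c2 = 5e4)
    regions <- GRanges(c("c1", "c2"), IRanges(1, c(1e5, 5e4)))
    loci <- lociGR(c("c1", "c1", "c2"), c(10, 500, 100),
                   c(20, 600, 200))
    res <- suppressWarnings(
        permutationTest(loci, regions, sizes, nPerm = 200, seed = 1))
    expect_equal(res@observedMeanDistance, 0)
    expect_true(all(res@nullMeans == 0))
    expect_equal(res@pPerm, 1)
})

test_that("the permutation null matches exhaustive enumeration on a toy genome", {
    ## 10-unit genome, one 1-unit region, one locus: placements start at
    ## 0..9, each equally likely
    sizes <- c(c1 = 10)
    regions <- GRanges("c1", IRanges(3, 3))   # 0-based [2,3)
    loci <- lociGR("c1", 5, 6, counts = 5)
    mcols(loci)$expression_rank <- 1L
    nPerm <- 20000
    res <- suppressWarnings(
        permutationTest(loci, regions, sizes, nPerm = nPerm, seed = 2,
                        mode = "regions", rankFilter = 1))
    ## exhaustive: region start0 in 0..9, gap distance to locus [5,6)
    expected <- sapply(0:9, function(s0) max(s0 - 6, 5 - (s0 + 1), 0))
    expect_setequal(unique(res@nullMeans), unique(expected))
    tab <- table(res@nullMeans) / nPerm
    expTab <- table(expected) / 10
    expect_equal(as.numeric(tab[names(expTab)]), as.numeric(expTab),
                 tolerance = 0.05)
    ## p bounds and determinism invariants
    expect_gte(res@pPerm, 1 / (nPerm + 1))
    expect_lte(res@pPerm, 1)
    res2 <- suppressWarnings(
        permutationTest(loci, regions, sizes, nPerm = nPerm, seed = 2,
                        mode = "regions", rankFilter = 1))
    expect_identical(res@nullMeans, res2@nullMeans)
})

test_that("an interval longer than every chromosome cannot be placed", {
    sizes <- c(c1 = 1000)
    regions <- GRanges("c1", IRanges(1, 1000))
    loci <- lociGR("c1", c(10, 50, 100), c(2000, 80, 130))
    expect_error(permutationTest(loci, regions, sizes, nPerm = 100,
                                 seed = 1, mode = "loci"),
                 "longer than every chromosome")
})

test_that("rank subsets share their permutation null under one seed", {
    cfg <- simulationConfig()
    cfg$dciSpec <- randomDciSpec(cfg, n = 8, seed = 3)
    regions <- dciSpecRegions(cfg)
    loci <- simulateExpressedLoci(cfg, truth = list(dcis = regions),
                                  seed = 4)
    both <- rankSubsetAnalysis(loci, regions, cfg$chromLengths,
                               nPerm = 300, seed = 5)
    expect_named(both, c("ranks1_2", "ranks1_4"))
    ## same placements: full-set run from permutationTest agrees exactly
    solo <- permutationTest(loci, regions, cfg$chromLengths, nPerm = 300,
                            seed = 5, rankFilter = 1:4)
    expect_identical(both$ranks1_4@nullMeans, solo@nullMeans)
    expect_identical(both$ranks1_4@pPerm, solo@pPerm)
    expect_error(rankSubsetAnalysis(loci, regions, cfg$chromLengths,
                                    rankSets = list(), nPerm = 300),
                 "non-empty")
    expect_error(rankSubsetAnalysis(loci, regions, cfg$chromLengths,
                                    rankSets = list(a = integer()),
                                    nPerm = 300),
                 "empty rank set")
})

test_that("association results serialize with their null distribution", {
    cfg <- simulationConfig()
    cfg$dciSpec <- randomDciSpec(cfg, n = 6, seed = 8)
    regions <- dciSpecRegions(cfg)
    loci <- simulateExpressedLoci(cfg, truth = list(dcis = regions),
                                  seed = 9)
    res <- permutationTest(loci, regions, cfg$chromLengths, nPerm = 150,
                           seed = 10)
    f <- withr::local_tempfile(fileext = ".json")
    writeAssociation(res, f)
    back <- jsonlite::read_json(f, simplifyVector = TRUE)
    expect_equal(back$p_perm, res@pPerm)
    expect_length(back$null_means, 150)
    expect_equal(back$n, res@n)
})
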