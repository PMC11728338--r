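test_that("Hi-C Pro triplets are mirrored into a symmetric matrix", {
    d <- withr::local_tempdir()
    writeLines(c("c1\t0\t100\t1", "c1\t100\t200\t2"),
               file.path(d, "bins.bed"))
    writeLines("1 2 5", file.path(d, "m.matrix"))
    m <- readHicproMatrix(file.path(d, "bins.bed"), file.path(d, "m.matrix"))
    expect_equal(contacts(m)[1, 2], 5)
    expect_equal(contacts(m)[2, 1], 5)
    expect_true(Matrix::isSymmetric(contacts(m), tol = 0))
})

test_that("matrix files violating referential integrity are rejected", {
    d <- withr::local_tempdir()
    writeLines(c("c1\t0\t100\t1", "c1\t100\t200\t2"),
               file.path(d, "bins.bed"))
    writeLines(c("1 2 5", "1 99 3"), file.path(d, "bad.matrix"))
    expect_error(readHicproMatrix(file.path(d, "bins.bed"),
                                  file.path(d, "bad.matrix")),
                 "line 2.*99")
    writeLines("1 2 -4", file.path(d, "neg.matrix"))
    expect_error(readHicproMatrix(file.path(d, "bins.bed"),
                                  file.path(d, "neg.matrix")),
                 "negative")
    writeLines(c("1 2 5", "2 1 5"), file.path(d, "dup.matrix"))
    expect_error(readHicproMatrix(file.path(d, "bins.bed"),
                                  file.path(d, "dup.matrix")),
                 "duplicate")
})

test_that("write/read round-trip is the identity on a random sparse matrix", {
    m0 <- toyContactMatrix(randomCounts(50, seed = 1))
    d <- withr::local_tempdir()
    writeHicproMatrix(m0, file.path(d, "b.bed"), file.path(d, "m.matrix"))
    m1 <- readHicproMatrix(file.path(d, "b.bed"), file.path(d, "m.matrix"))
    expect_true(all(contacts(m0) == contacts(m1)))
    expect_equal(start(bins(m0)), start(bins(m1)))
    expect_equal(end(bins(m0)), end(bins(m1)))
    ## written triplets are upper-triangle only, sorted
    tr <- read.table(file.path(d, "m.matrix"))
    expect_true(all(tr$V1 <= tr$V2))
    expect_false(is.unsorted(tr$V1))
})

test_that("a 2-bin matrix emits exactly one triplet line", {
    mat <- matrix(c(0, 5, 5, 0), 2, 2)
    d <- withr::local_tempdir()
    writeHicproMatrix(toyContactMatrix(mat), file.path(d, "b.bed"),
                      file.path(d, "m.matrix"))
    expect_identical(readLines(file.path(d, "m.matrix")), "1 2 5")
    ## empty matrix: empty triplet file, valid bins file
    writeHicproMatrix(toyContactMatrix(matrix(0, 2, 2)),
                      file.path(d, "b2.bed"), file.path(d, "m2.matrix"))
    expect_identical(readLines(file.path(d, "m2.matrix")), character(0))
    expect_length(readLines(file.path(d, "b2.bed")), 2L)
})

test_that("BED records parse with coordinates converted and errors located", {
    f <- withr::local_tempfile(fileext = ".bed")
    writeLines("chr1\t10\t20\tx\t3.5", f)
    gr <- readBed(f)
    expect_equal(start(gr), 11)
    expect_equal(end(gr), 20)
    expect_equal(mcols(gr)$name, "x")
    expect_equal(mcols(gr)$score, 3.5)

    writeLines(c("chr1\t1\t5", "chr1\t20\t10"), f)
    expect_error(readBed(f), "line 2")
    writeLines("chr1\tfoo\t5", f)
    expect_error(readBed(f), "non-numeric")
})

test_that("BED write/read round-trips 100 random intervals", {
    gr <- withr::with_seed(2, {
        s <- sample.int(1e6, 100)
        g <- GRanges(sample(c("chr1", "chr2"), 100, replace = TRUE),
                     IRanges(s + 1, s + sample.int(5000, 100)))
        mcols(g)$name <- sprintf("iv%03d", 1:100)
        mcols(g)$score <- round(runif(100), 3)
        g
    })
    f <- withr::local_tempfile(fileext = ".bed")
    writeBed(gr, f)
    back <- readBed(f)
    expect_equal(start(back), start(gr))
    expect_equal(end(back), end(gr))
    expect_equal(mcols(back)$name, mcols(gr)$name)
    expect_equal(mcols(back)$score, mcols(gr)$score)
})

test_that("loci tables round-trip and quartile ranks partition by expression", {
    cnt <- c(100, 90, 80, 70, 60, 50, 40, 30, 25, 20, 18, 16, 14, 12, 10,
             8, 6, 4, 2)
    r <- expressionRanks(cnt)
    expect_setequal(unique(r), 1:4)
    ## descending counts map to non-decreasing ranks
    expect_true(all(diff(r[order(-cnt)]) >= 0))
    expect_equal(as.integer(table(r)), c(4L, 5L, 5L, 5L))

    gr <- GRanges("chr1", IRanges(seq(1, by = 1e4, length.out = 19),
                                  width = 9000))
    mcols(gr)$name <- sprintf("l%02d", 1:19)
    mcols(gr)$normalized_count <- cnt
    mcols(gr)$expression_rank <- r
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLociTable(gr, f)
    back <- readLociTable(f)
    expect_equal(mcols(back)$normalized_count, cnt)
    expect_equal(mcols(back)$expression_rank, r)
    expect_equal(start(back), start(gr))
})

test_that("chromosome sizes files validate and round-trip", {
    f <- withr::local_tempfile()
    writeChromSizes(c(chr1 = 1000, chr2 = 500), f)
    expect_equal(readChromSizes(f), c(chr1 = 1000, chr2 = 500))
    writeLines(c("chr1\t100", "chr1\t200"), f)
    expect_error(readChromSizes(f), "duplicated")
    writeLines("chr1\t-5", f)
    expect_error(readChromSizes(f), "> 0")
})
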