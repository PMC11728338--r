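#' @importFrom data.table fread fwrite data.table setkey :=
#' @importFrom Matrix sparseMatrix forceSymmetric
NULL

## construct a ContactMatrix from a bin GRanges and a symmetric sparse matrix
newContactMatrix <- function(bins, counts, normalized = FALSE,
                             bias = NULL, masked = NULL) {
    n <- length(bins)
    if (is.null(mcols(bins)$bin_id))
        mcols(bins)$bin_id <- seq_len(n)
    if (is.null(bias)) bias <- rep(NA_real_, n)
    if (is.null(masked)) masked <- rep(FALSE, n)
    new("ContactMatrix", bins = bins, counts = forceSymmetric(counts),
        normalized = normalized, bias = bias, masked = masked)
}

## row indices of the bins of one chromosome, in order
chromIndices <- function(m, chrom) {
    idx <- which(as.character(seqnames(bins(m))) == chrom)
    if (!length(idx))
        stop("chromosome '", chrom, "' not present in the contact matrix")
    idx
}

## dense intra-chromosomal contact block
chromDense <- function(m, chrom) {
    idx <- chromIndices(m, chrom)
    as.matrix(contacts(m)[idx, idx, drop = FALSE])
}

chromNames <- function(m) unique(as.character(seqnames(bins(m))))

#' Read a Hi-C Pro sparse-triplet contact matrix
#'
#' Hi-C Pro emits a bins BED file (\code{<prefix>_abs.bed}: chrom, 0-based
#' start, end, bin id) and a whitespace-separated triplet file
#' (\code{<prefix>.matrix}: bin id i, bin id j, value) holding the upper
#' triangle. The matrix is symmetrized on read; bin ids are resolved against
#' the bins file, so any consistent id convention (Hi-C Pro uses 1-based)
#' works.
#'
#' @param binsPath path to the bins BED file.
#' @param matrixPath path to the triplet file.
#' @return a \linkS4class{ContactMatrix}.
#' @examples
#' d <- tempfile(); dir.create(d)
#' writeLines(c("chr1\t0\t100\t1", "chr1\t100\t200\t2"),
#'            file.path(d, "bins.bed"))
#' writeLines("1 2 5", file.path(d, "mat.matrix"))
#' m <- readHicproMatrix(file.path(d, "bins.bed"), file.path(d, "mat.matrix"))
#' contacts(m)[1, 2]
#' @export
readHicproMatrix <- function(binsPath, matrixPath) {
    bt <- fread(binsPath, header = FALSE, sep = "\t",
                col.names = c("chrom", "start", "end", "bin_id"))
    if (ncol(bt) < 4L)
        stop("bins file must have 4 columns (chrom, start, end, bin_id)")
    if (any(bt$start >= bt$end))
        stop("bins file contains an interval with start >= end")
    gr <- GRanges(bt$chrom, IRanges(bt$start + 1L, bt$end))
    mcols(gr)$bin_id <- seq_along(gr)
    idmap <- seq_along(gr)
    names(idmap) <- as.character(bt$bin_id)

    tr <- fread(matrixPath, header = FALSE,
                col.names = c("i", "j", "value"))
    n <- length(gr)
    if (nrow(tr)) {
        ri <- idmap[as.character(tr$i)]
        rj <- idmap[as.character(tr$j)]
        bad <- which(is.na(ri) | is.na(rj))
        if (length(bad))
            stop("matrix line ", bad[1L], ": unknown bin_id '",
                 ifelse(is.na(ri[bad[1L]]), tr$i[bad[1L]], tr$j[bad[1L]]),
                 "' not present in the bins file")
        neg <- which(tr$value < 0)
        if (length(neg))
            stop("matrix line ", neg[1L], ": negative contact value")
        lo <- pmin(ri, rj); hi <- pmax(ri, rj)
        key <- (lo - 1) * as.double(n) + hi
        if (anyDuplicated(key))
            stop("matrix line ", which(duplicated(key))[1L],
                 ": duplicate entry for bin pair (",
                 tr$i[which(duplicated(key))[1L]], ", ",
                 tr$j[which(duplicated(key))[1L]], ")")
        cm <- sparseMatrix(i = lo, j = hi, x = as.double(tr$value),
                           dims = c(n, n), symmetric = TRUE)
    } else {
        cm <- sparseMatrix(i = integer(), j = integer(), x = double(),
                           dims = c(n, n), symmetric = TRUE)
    }
    newContactMatrix(gr, cm)
}

#' Write a ContactMatrix in Hi-C Pro sparse-triplet format
#'
#' Emits the bins BED file in bin order with 1-based bin ids (the Hi-C Pro
#' convention) and the upper triangle (including the diagonal) of the contact
#' matrix sorted by (i, j).
#'
#' @param m a \linkS4class{ContactMatrix}.
#' @param binsPath,matrixPath output paths.
#' @return invisibly, the two paths.
#' @export
writeHicproMatrix <- function(m, binsPath, matrixPath) {
    g <- bins(m)
    bt <- data.table(chrom = as.character(seqnames(g)),
                     start = start(g) - 1L, end = end(g),
                     bin_id = seq_along(g))
    fwrite(bt, binsPath, sep = "\t", col.names = FALSE)
    tm <- methods::as(contacts(m), "TsparseMatrix")
    keep <- tm@i <= tm@j
    dt <- data.table(i = tm@i[keep] + 1L, j = tm@j[keep] + 1L,
                     value = tm@x[keep])
    dt <- dt[order(i, j)]
    dt[, value := sprintf("%.17g", value)]
    fwrite(dt, matrixPath, sep = " ", col.names = FALSE, quote = FALSE)
    invisible(c(bins = binsPath, matrix = matrixPath))
}

#' Read and write BED interval files
#'
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' convention of \code{GRanges} on read and back on write. Optional columns 4
#' (name), 5 (score) and 6 (strand) are carried through.
#'
#' @param path a BED3+ tab-separated file.
#' @return \code{readBed}: a \code{GRanges}, with \code{name}/\code{score}
#'   metadata columns when present.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t10\t20\tx\t3.5", f)
#' readBed(f)
#' @export
readBed <- function(path) {
    dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
    if (ncol(dt) < 3L) stop("BED file must have at least 3 columns")
    s <- suppressWarnings(as.numeric(dt[[2L]]))
    e <- suppressWarnings(as.numeric(dt[[3L]]))
    bad <- which(is.na(s) | is.na(e))
    if (length(bad))
        stop("line ", bad[1L], ": non-numeric coordinate")
    bad <- which(s >= e)
    if (length(bad))
        stop("line ", bad[1L], ": start >= end (", s[bad[1L]], " >= ",
             e[bad[1L]], ")")
    if (any(s < 0)) stop("negative start coordinate")
    gr <- GRanges(dt[[1L]], IRanges(s + 1, e))
    if (ncol(dt) >= 4L) mcols(gr)$name <- as.character(dt[[4L]])
    if (ncol(dt) >= 5L) mcols(gr)$score <- as.numeric(dt[[5L]])
    if (ncol(dt) >= 6L) {
        st <- as.character(dt[[6L]])
        st[!st %in% c("+", "-")] <- "*"
        strand(gr) <- st
    }
    gr
}

#' @rdname readBed
#' @param gr a \code{GRanges} to write.
#' @export
writeBed <- function(gr, path) {
    dt <- data.table(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr))
    hasName <- !is.null(mcols(gr)$name)
    hasScore <- !is.null(mcols(gr)$score)
    if (hasName || hasScore) {
        dt$name <- if (hasName) as.character(mcols(gr)$name) else "."
        if (hasScore) {
            dt$score <- mcols(gr)$score
            dt$strand <- as.character(strand(gr))
            dt$strand[dt$strand == "*"] <- "."
        }
    }
    fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a chromosome-sizes table
#'
#' @param path two-column tab-separated file (chrom, length in bp).
#' @return named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    dt <- fread(path, header = FALSE, sep = "\t")
    if (ncol(dt) < 2L) stop("chrom.sizes must have 2 columns")
    len <- as.numeric(dt[[2L]])
    if (any(is.na(len) | len <= 0)) stop("chromosome lengths must be > 0")
    nm <- as.character(dt[[1L]])
    if (anyDuplicated(nm)) stop("duplicated chromosome name")
    stats::setNames(len, nm)
}

#' @rdname readChromSizes
#' @param sizes named numeric vector of lengths.
#' @export
writeChromSizes <- function(sizes, path) {
    fwrite(data.table(chrom = names(sizes), length = as.integer(sizes)),
           path, sep = "\t", col.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read and write tables of expressed loci
#'
#' The loci table is a headered TSV with columns chrom, start (0-based), end,
#' name, normalized_count and optionally expression_rank; missing ranks are
#' computed by [expressionRanks()].
#'
#' @param path TSV path.
#' @return \code{readLociTable}: a \code{GRanges} with \code{name},
#'   \code{normalized_count} and \code{expression_rank} columns.
#' @export
readLociTable <- function(path) {
    dt <- fread(path, header = TRUE, sep = "\t")
    need <- c("chrom", "start", "end", "name", "normalized_count")
    if (!all(need %in% names(dt)))
        stop("loci table must have columns: ", paste(need, collapse = ", "))
    if (any(dt$start >= dt$end)) stop("locus with start >= end")
    if (any(dt$normalized_count <= 0))
        stop("normalized_count must be > 0")
    gr <- GRanges(dt$chrom, IRanges(dt$start + 1, dt$end))
    mcols(gr)$name <- as.character(dt$name)
    mcols(gr)$normalized_count <- as.numeric(dt$normalized_count)
    mcols(gr)$expression_rank <-
        if ("expression_rank" %in% names(dt)) as.integer(dt$expression_rank)
        else expressionRanks(mcols(gr)$normalized_count)
    gr
}

#' @rdname readLociTable
#' @param loci a loci \code{GRanges} as returned by [readLociTable()] or
#'   [simulateExpressedLoci()].
#' @export
writeLociTable <- function(loci, path) {
    dt <- data.table(chrom = as.character(seqnames(loci)),
                     start = start(loci) - 1L, end = end(loci),
                     name = mcols(loci)$name,
                     normalized_count = mcols(loci)$normalized_count,
                     expression_rank = mcols(loci)$expression_rank)
    fwrite(dt, path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Quartile expression ranks
#'
#' Rank 1 holds the top quartile of loci by normalized expression, rank 4 the
#' lowest; loci are ordered by descending count and rank =
#' \code{ceiling(4 * position / n)}.
#'
#' @param counts positive normalized expression values.
#' @return integer ranks in \code{1:4}.
#' @export
expressionRanks <- function(counts) {
    n <- length(counts)
    pos <- integer(n)
    pos[order(-counts)] <- seq_len(n)
    as.integer(ceiling(4 * pos / n))
}
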