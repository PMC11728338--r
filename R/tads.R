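#' Per-bin contact-profile features for TAD calling
#'
#' Each bin of a chromosome is described by the log1p of its decay-corrected
#' (observed/expected) contact profile to the bins within
#' \code{windowBins} of it, kept in absolute chromosome coordinates (entries
#' beyond the band are zero), where the expected value at separation d is the
#' mean contact over the d-th diagonal. Bins of the same domain share
#' elevated contact to the same stretch of the chromosome, so their profiles
#' cluster together; the decay correction removes the dominant distance trend
#' and the band suppresses the long-range entries that carry no domain
#' signal. Bins masked during balancing inherit the profile of their nearest
#' unmasked neighbour so that low-coverage edges do not form artificial
#' domains.
#'
#' @param m a normalized \linkS4class{ContactMatrix}.
#' @param chrom chromosome to extract.
#' @param windowBins band half-width in bins.
#' @return numeric matrix, one row of features per bin.
#' @export
extractFeatures <- function(m, chrom, windowBins = 10L) {
    stopifnot(is(m, "ContactMatrix"))
    if (!isNormalized(m))
        stop("contact matrix must be ICE-normalized before TAD calling")
    if (windowBins < 2L) stop("windowBins must be at least 2")
    oe <- chromOE(m, chrom)
    n <- nrow(oe)
    feat <- log1p(oe)
    d <- abs(.row(c(n, n)) - .col(c(n, n)))
    feat[d > windowBins] <- 0
    idx <- chromIndices(m, chrom)
    msk <- which(m@masked[idx])
    if (length(msk) && length(msk) < n) {
        unm <- setdiff(seq_len(n), msk)
        for (i in msk) {
            j <- unm[which.min(abs(unm - i))]
            feat[i, ] <- feat[j, ]
        }
    }
    feat
}

## decay-corrected contact map of one chromosome
chromOE <- function(m, chrom) {
    observedOverExpected(chromDense(m, chrom))
}

## divide each diagonal by its mean (expected contact at that separation)
observedOverExpected <- function(mat) {
    n <- nrow(mat)
    d <- abs(.row(dim(mat)) - .col(dim(mat)))
    expd <- vapply(split(as.vector(mat), as.vector(d)), mean, numeric(1))
    E <- matrix(expd[as.character(d)], n, n)
    out <- mat / pmax(E, .Machine$double.eps)
    out[E == 0] <- 0
    out
}

#' Segment a chromosome into candidate TADs by clustering
#'
#' Bins are clustered into \code{k} groups by k-means (fixed seed, multiple
#' restarts) on their contact-profile features; maximal runs of consecutive
#' bins sharing a cluster label become candidate domains, and runs shorter
#' than \code{minTadBins} are merged into the neighbouring run whose centroid
#' is more similar.
#'
#' @param m a normalized \linkS4class{ContactMatrix}.
#' @param chrom chromosome name.
#' @param k number of clusters, \code{2 <= k <= n_bins / 2}.
#' @param seed clustering seed (recorded in the result).
#' @param minTadBins minimum domain size in bins.
#' @param windowBins feature band half-width, see [extractFeatures()].
#' @param features optional precomputed [extractFeatures()] matrix.
#' @return a \linkS4class{TADSet} (quality slot unset; see [tadQuality()]).
#' @export
segmentByClustering <- function(m, chrom, k, seed = 0L, minTadBins = 2L,
                                windowBins = 10L, features = NULL) {
    if (is.null(features)) features <- extractFeatures(m, chrom, windowBins)
    n <- nrow(features)
    if (k < 2 || k > n / 2)
        stop("k = ", k, " out of range [2, ", floor(n / 2), "]")
    ## kmeans may warn about slow Quick-TRANSfer convergence on
    ## structureless data; the restarts still return a deterministic fit
    km <- withr::with_seed(as.integer(seed),
        suppressWarnings(stats::kmeans(features, centers = k, nstart = 10L,
                                       iter.max = 100L)))
    runs <- rle(km$cluster)
    runs <- mergeShortRuns(runs, features, km$centers, minTadBins)
    idx <- chromIndices(m, chrom)
    binStarts <- start(bins(m))[idx]
    binEnds <- end(bins(m))[idx]
    ends <- cumsum(runs$lengths)
    starts <- c(1L, ends[-length(ends)] + 1L)
    gr <- GRanges(chrom, IRanges(binStarts[starts], binEnds[ends]))
    mcols(gr)$quality <- NA_real_
    new("TADSet", chrom = chrom, tads = gr, kSelected = as.integer(k),
        quality = NA_real_, seed = as.integer(seed))
}

## merge runs shorter than minLen into the neighbouring run with the closer
## cluster centroid
mergeShortRuns <- function(runs, features, centers, minLen) {
    repeat {
        if (length(runs$lengths) <= 1L) break
        short <- which(runs$lengths < minLen)
        if (!length(short)) break
        i <- short[1L]
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1L
        segMean <- colMeans(features[starts[i]:ends[i], , drop = FALSE])
        cand <- c(if (i > 1L) i - 1L, if (i < length(runs$lengths)) i + 1L)
        d2 <- vapply(cand, function(j)
            sum((segMean - centers[runs$values[j], ])^2), numeric(1))
        runs$values[i] <- runs$values[cand[which.min(d2)]]
        runs <- rle(inverse.rle(runs))
    }
    runs
}

#' Contrast quality of a domain partition
#'
#' The score is the mean decay-corrected contact (observed/expected) over
#' intra-domain bin pairs minus the mean over inter-domain pairs at
#' separations up to the largest domain size of the partition. Because the
#' expected value at every separation is the diagonal mean, O/E has unit
#' expectation at any separation, so the score is centred at 0 for an
#' uninformative partition: a uniform matrix scores 0 for every partition,
#' and the planted partition of a block-enriched matrix scores higher than
#' any shifted partition.
#'
#' @param m a normalized \linkS4class{ContactMatrix}.
#' @param tset a \linkS4class{TADSet} covering the chromosome.
#' @param oe optional precomputed decay-corrected (observed/expected) matrix
#'   of the chromosome.
#' @return a single numeric quality.
#' @export
tadQuality <- function(m, tset, oe = NULL) {
    stopifnot(is(tset, "TADSet"))
    if (!length(tads(tset))) stop("empty TADSet")
    if (is.null(oe)) oe <- chromOE(m, tset@chrom)
    n <- nrow(oe)
    idx <- chromIndices(m, tset@chrom)
    lab <- binTadLabels(bins(m)[idx], tset)
    maxSize <- max(as.integer(round(width(tads(tset)) /
                                    binResolution(m))))
    d <- abs(.row(c(n, n)) - .col(c(n, n)))
    same <- outer(lab, lab, "==")
    intra <- same & d > 0
    inter <- (!same) & d > 0 & d <= maxSize
    if (!any(intra) || !any(inter)) return(0)
    mean(oe[intra]) - mean(oe[inter])
}

## assign each bin to the domain containing its midpoint (0 = none)
binTadLabels <- function(binGr, tset) {
    mid <- (start(binGr) + end(binGr)) / 2
    g <- tads(tset)
    lab <- findInterval(mid, start(g))
    lab[mid > end(g)[pmax(lab, 1L)]] <- 0L
    lab[lab == 0L] <- NA_integer_
    lab
}

#' Call the best-scoring TAD partition of each chromosome
#'
#' Runs [segmentByClustering()] for each candidate number of clusters, scores
#' every candidate partition with [tadQuality()] and returns the arg-max, with
#' ties broken toward the smaller k. A single domain spanning the chromosome
#' (quality 0) is always among the candidates, so chromosomes without
#' domain structure beyond noise level are returned unsegmented.
#'
#' @param m a normalized \linkS4class{ContactMatrix}.
#' @param kRange integer candidate cluster numbers; default
#'   \code{2:min(40, n_bins \%/\% 4)}.
#' @param minTadBins minimum domain size in bins.
#' @param windowBins feature band half-width, see [extractFeatures()].
#' @param seed clustering seed.
#' @return named list of \linkS4class{TADSet}, one per chromosome.
#' @examples
#' cfg <- simulationConfig(chromLengths = c(chrS1 = 1e7),
#'                         tadSizeRange = c(10, 20))
#' m <- iceNormalize(simulateMatrix(cfg, seed = 5)$matrix)
#' callBestTads(m, kRange = 2:6)
#' @export
callBestTads <- function(m, kRange = NULL, minTadBins = 2L,
                         windowBins = 10L, seed = 0L) {
    stopifnot(is(m, "ContactMatrix"))
    out <- lapply(chromNames(m), function(ch) {
        feat <- extractFeatures(m, ch, windowBins)
        oe <- chromOE(m, ch)
        n <- nrow(feat)
        kr <- if (is.null(kRange)) seq(2L, max(2L, min(40L, n %/% 4L)))
              else kRange
        if (!length(kr)) stop("empty kRange")
        ## baseline candidate: one domain spanning the chromosome
        ## (quality 0 by construction); clustered partitions must beat it
        idx <- chromIndices(m, ch)
        base <- GRanges(ch, IRanges(min(start(bins(m))[idx]),
                                    max(end(bins(m))[idx])))
        mcols(base)$quality <- 0
        best <- new("TADSet", chrom = ch, tads = base, kSelected = 1L,
                    quality = 0, seed = as.integer(seed))
        bestQ <- 0
        for (k in sort(unique(as.integer(kr)))) {
            cand <- tryCatch(
                segmentByClustering(m, ch, k, seed = seed,
                                    minTadBins = minTadBins,
                                    features = feat),
                error = function(e) NULL)
            if (is.null(cand)) next
            q <- tadQuality(m, cand, oe = oe)
            if (q > bestQ + 1e-12) {
                bestQ <- q
                best <- cand
            }
        }
        best@quality <- bestQ
        mcols(best@tads)$quality <- bestQ
        best
    })
    names(out) <- chromNames(m)
    out
}

#' Boundary recovery of a called partition against a reference
#'
#' Internal boundaries (domain breakpoints excluding the chromosome ends) are
#' matched at a tolerance of \code{tolBins} bins; precision is the fraction of
#' called boundaries near a reference boundary, recall the fraction of
#' reference boundaries near a called one.
#'
#' @param called,reference \linkS4class{TADSet} objects for the same
#'   chromosome.
#' @param resolution bin width in bp.
#' @param tolBins matching tolerance in bins.
#' @return named numeric vector with precision, recall and f1.
#' @export
boundaryStats <- function(called, reference, resolution, tolBins = 1) {
    pb <- internalBoundaries(called)
    tb <- internalBoundaries(reference)
    tol <- tolBins * resolution
    if (!length(pb) || !length(tb)) {
        f <- as.numeric(length(pb) == length(tb))
        return(c(precision = f, recall = f, f1 = f))
    }
    prec <- mean(vapply(pb, function(b) any(abs(tb - b) <= tol), logical(1)))
    rec <- mean(vapply(tb, function(b) any(abs(pb - b) <= tol), logical(1)))
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1)
}

internalBoundaries <- function(tset) {
    b <- boundaries(tset)
    if (length(b) <= 2L) return(numeric())
    b[-c(1L, length(b))]
}

#' Write TAD calls as BED6 and boundaries as TSV
#'
#' @param tadsets named list of \linkS4class{TADSet} (one per chromosome).
#' @param bedPath,tsvPath output paths (either may be \code{NULL}).
#' @return invisibly, the written paths.
#' @export
writeTadBed <- function(tadsets, bedPath = NULL, tsvPath = NULL) {
    rows <- lapply(tadsets, function(ts) {
        g <- tads(ts)
        data.table(chrom = as.character(seqnames(g)), start = start(g) - 1L,
                   end = end(g),
                   name = sprintf("%s_tad%03d", ts@chrom, seq_along(g)),
                   score = round(mcols(g)$quality, 6), strand = ".")
    })
    bed <- data.table::rbindlist(rows)
    if (!is.null(bedPath))
        fwrite(bed, bedPath, sep = "\t", col.names = FALSE, quote = FALSE)
    if (!is.null(tsvPath)) {
        brows <- lapply(tadsets, function(ts)
            data.table(chrom = ts@chrom, boundary = boundaries(ts),
                       k_selected = ts@kSelected))
        fwrite(data.table::rbindlist(brows), tsvPath, sep = "\t",
               quote = FALSE)
    }
    invisible(c(bed = bedPath, tsv = tsvPath))
}
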