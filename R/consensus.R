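#' @importFrom GenomicRanges coverage reduce findOverlaps
#' @importFrom IRanges slice
NULL

#' Intersect DCI regions across replicates
#'
#' Genomic positions covered by regions in at least \code{minSupport}
#' replicates are merged into maximal consensus intervals. Each consensus
#' interval records the number and identity of the replicates whose regions
#' overlap it. With the default \code{minSupport} (all replicates) this is the
#' strict positional intersection: a region must be supported by every
#' replicate pair to count as conserved.
#'
#' @param dciSets list (length >= 2) of \code{GRanges}, one per replicate,
#'   all of the same direction.
#' @param minSupport minimum number of supporting replicates; defaults to all.
#' @return \code{GRanges} of consensus intervals with \code{support} and
#'   \code{supporters} columns.
#' @export
intersectReplicates <- function(dciSets, minSupport = length(dciSets)) {
    if (!length(dciSets)) stop("no replicate DCI sets given")
    if (length(dciSets) < 2L) stop("need at least 2 replicate DCI sets")
    stopifnot(minSupport >= 1, minSupport <= length(dciSets))
    covs <- lapply(dciSets, function(g) coverage(reduce(g)))
    lvls <- unique(unlist(lapply(covs, names)))
    total <- NULL
    for (cv in covs) {
        missing <- setdiff(lvls, names(cv))
        for (mchr in missing) cv[[mchr]] <- S4Vectors::Rle(0L, 0L)
        cv <- cv[lvls]
        total <- if (is.null(total)) cv else {
            ## pad runs to equal length before adding
            for (ch in lvls) {
                la <- length(total[[ch]]); lb <- length(cv[[ch]])
                if (la < lb) total[[ch]] <- c(total[[ch]],
                                              S4Vectors::Rle(0L, lb - la))
                if (lb < la) cv[[ch]] <- c(cv[[ch]],
                                           S4Vectors::Rle(0L, la - lb))
            }
            total + cv
        }
    }
    sl <- slice(total, lower = minSupport, rangesOnly = TRUE)
    cons <- GRanges(sl)
    if (!length(cons)) {
        mcols(cons)$support <- integer()
        return(cons)
    }
    supporters <- lapply(seq_along(cons), function(i) {
        which(vapply(dciSets, function(g)
            length(findOverlaps(cons[i], g)) > 0, logical(1)))
    })
    mcols(cons)$support <- lengths(supporters)
    mcols(cons)$supporters <- vapply(supporters, paste, character(1),
                                     collapse = ",")
    sort(cons)
}

#' Keep consensus DCIs close to TAD boundaries in every replicate
#'
#' For each consensus interval the gap distance to the nearest TAD boundary
#' is computed per replicate; intervals whose distance exceeds
#' \code{maxDistance} in any replicate are dropped. Boundary positions are
#' the domain breakpoints (bp); an interval containing a boundary has
#' distance 0.
#'
#' @param cons consensus \code{GRanges} from [intersectReplicates()].
#' @param tadsets list over replicates; each element a named list of
#'   \linkS4class{TADSet} per chromosome (as from [callBestTads()]).
#' @param maxDistance maximum allowed gap distance in bp (default one 100-kb
#'   bin).
#' @return the retained \code{GRanges} with one \code{dist_repN} column per
#'   replicate.
#' @export
matchToTadBoundaries <- function(cons, tadsets, maxDistance = 1e5) {
    if (!length(cons)) return(cons)
    nrep <- length(tadsets)
    dmat <- matrix(NA_real_, length(cons), nrep)
    chs <- as.character(seqnames(cons))
    for (r in seq_len(nrep)) {
        for (ch in unique(chs)) {
            ts <- tadsets[[r]][[ch]]
            if (is.null(ts))
                stop("chromosome '", ch, "' missing from replicate ", r,
                     " TAD calls")
            b <- boundaries(ts)
            sel <- which(chs == ch)
            s0 <- start(cons)[sel] - 1
            e0 <- end(cons)[sel]
            dmat[sel, r] <- vapply(seq_along(sel), function(i) {
                d <- ifelse(b >= s0[i] & b <= e0[i], 0,
                            pmin(abs(b - s0[i]), abs(b - e0[i])))
                min(d)
            }, numeric(1))
        }
    }
    colnames(dmat) <- paste0("dist_rep", seq_len(nrep))
    keep <- apply(dmat, 1L, max) <= maxDistance
    out <- cons[keep]
    for (r in seq_len(nrep))
        mcols(out)[[colnames(dmat)[r]]] <- dmat[keep, r]
    out
}

#' Write consensus DCIs as BED6 plus a support/distances TSV
#'
#' @param cons consensus \code{GRanges} (optionally after
#'   [matchToTadBoundaries()]).
#' @param bedPath,tsvPath output paths (either may be \code{NULL}).
#' @return invisibly, the written paths.
#' @export
writeConsensus <- function(cons, bedPath = NULL, tsvPath = NULL) {
    dt <- data.table(chrom = as.character(seqnames(cons)),
                     start = start(cons) - 1L, end = end(cons),
                     name = sprintf("consensus%03d", seq_along(cons)),
                     score = mcols(cons)$support, strand = ".")
    if (!is.null(bedPath))
        fwrite(dt, bedPath, sep = "\t", col.names = FALSE, quote = FALSE)
    if (!is.null(tsvPath)) {
        extra <- as.data.frame(mcols(cons))
        fwrite(cbind(dt[, c("chrom", "start", "end", "name")], extra),
               tsvPath, sep = "\t", quote = FALSE)
    }
    invisible(c(bed = bedPath, tsv = tsvPath))
}
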