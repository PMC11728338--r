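#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlevels seqlengths seqnames<-
NULL

#' ContactMatrix: a binned, symmetric Hi-C contact map
#'
#' Holds a genome-wide bin table together with a sparse symmetric matrix of
#' intra-chromosomal contact values. Bins are uniform-width genomic intervals
#' (the last bin of a chromosome may be shorter); \code{bin} indices are
#' 1-based row/column indices into \code{counts}.
#'
#' @slot bins \code{GRanges} of bins, sorted by (chromosome, start), with an
#'   integer \code{bin_id} metadata column equal to the row index.
#' @slot counts symmetric sparse \code{Matrix} of non-negative finite contact
#'   values, one row/column per bin.
#' @slot normalized logical; \code{TRUE} after ICE balancing.
#' @slot bias numeric vector of per-bin ICE bias factors (\code{NA_real_}
#'   before balancing).
#' @slot masked logical vector marking bins excluded from balancing because of
#'   low or zero coverage.
#'
#' @seealso [readHicproMatrix()], [iceNormalize()], [simulateMatrix()]
#' @export
setClass("ContactMatrix",
    representation(
        bins = "GRanges",
        counts = "Matrix",
        normalized = "logical",
        bias = "numeric",
        masked = "logical"
    )
)

setValidity("ContactMatrix", function(object) {
    n <- length(object@bins)
    msg <- character()
    if (nrow(object@counts) != n || ncol(object@counts) != n)
        msg <- c(msg, "counts dimensions must match the number of bins")
    if (is.null(mcols(object@bins)$bin_id))
        msg <- c(msg, "bins must carry a 'bin_id' metadata column")
    if (!Matrix::isSymmetric(object@counts, tol = 0))
        msg <- c(msg, "counts must be exactly symmetric")
    v <- object@counts@x
    if (length(v) && (any(!is.finite(v)) || any(v < 0)))
        msg <- c(msg, "contact values must be finite and >= 0")
    if (length(object@normalized) != 1L)
        msg <- c(msg, "normalized must be a single logical")
    if (length(object@masked) != n || length(object@bias) != n)
        msg <- c(msg, "bias and masked must have one entry per bin")
    if (length(msg)) msg else TRUE
})

#' TADSet: a non-overlapping domain partition of one chromosome
#'
#' @slot chrom chromosome name.
#' @slot tads \code{GRanges} of domains, sorted, non-overlapping, covering the
#'   chromosome, with a numeric \code{quality} metadata column.
#' @slot kSelected integer; the number of clusters behind this partition.
#' @slot quality numeric; contrast score of the partition (intra-domain minus
#'   inter-domain mean decay-corrected contact).
#' @slot seed integer; clustering seed recorded for reproducibility.
#' @export
setClass("TADSet",
    representation(
        chrom = "character",
        tads = "GRanges",
        kSelected = "integer",
        quality = "numeric",
        seed = "integer"
    )
)

setValidity("TADSet", function(object) {
    msg <- character()
    g <- object@tads
    if (length(object@chrom) != 1L)
        msg <- c(msg, "chrom must be a single chromosome name")
    if (length(g)) {
        if (!all(as.character(seqnames(g)) == object@chrom))
            msg <- c(msg, "all TADs must lie on 'chrom'")
        if (is.unsorted(start(g)))
            msg <- c(msg, "TADs must be sorted by start")
        if (length(g) > 1L && any(start(g)[-1L] <= end(g)[-length(g)]))
            msg <- c(msg, "TADs must not overlap")
    }
    if (length(msg)) msg else TRUE
})

#' DCIProfile: per-bin differential chromatin interaction scores
#'
#' Positive scores mark bins whose local contact neighbourhood is increased in
#' condition B relative to condition A.
#'
#' @slot profile \code{GRanges} of bins with a numeric \code{score} column.
#' @slot windowBins integer half-width (in bins) of the paired window used to
#'   compute each score.
#' @export
setClass("DCIProfile",
    representation(profile = "GRanges", windowBins = "integer")
)

setValidity("DCIProfile", function(object) {
    msg <- character()
    if (is.null(mcols(object@profile)$score))
        msg <- c(msg, "profile must carry a 'score' column")
    else if (any(!is.finite(mcols(object@profile)$score)))
        msg <- c(msg, "scores must be finite")
    if (length(object@windowBins) != 1L || object@windowBins < 1L)
        msg <- c(msg, "windowBins must be a single positive integer")
    if (length(msg)) msg else TRUE
})

#' AssociationResult: proximity association between loci and regions
#'
#' Bundles the Spearman rank association between locus expression and
#' locus-to-nearest-region distance with a genome-randomization permutation
#' test of the mean nearest distance.
#'
#' @slot n number of loci entering the statistics.
#' @slot rho Spearman rank correlation coefficient.
#' @slot pSpearman two-sided p-value of \code{rho} (t approximation).
#' @slot observedMeanDistance observed mean locus-to-nearest-region gap
#'   distance in bp.
#' @slot nullMeans numeric vector of permutation-null mean distances.
#' @slot pPerm one-sided permutation p-value, add-one estimator.
#' @slot nPerm number of permutations.
#' @slot seed integer seed of the permutation stream.
#' @slot mode which element set was randomized: \code{"regions"} or
#'   \code{"loci"}.
#' @slot rankFilter expression ranks retained before distance computation.
#' @export
setClass("AssociationResult",
    representation(
        n = "integer",
        rho = "numeric",
        pSpearman = "numeric",
        observedMeanDistance = "numeric",
        nullMeans = "numeric",
        pPerm = "numeric",
        nPerm = "integer",
        seed = "integer",
        mode = "character",
        rankFilter = "integer"
    )
)

setValidity("AssociationResult", function(object) {
    msg <- character()
    if (!is.na(object@pPerm) &&
        (object@pPerm <= 0 || object@pPerm > 1))
        msg <- c(msg, "pPerm must lie in (0, 1]")
    if (!is.na(object@rho) && abs(object@rho) > 1 + 1e-12)
        msg <- c(msg, "rho must lie in [-1, 1]")
    if (length(object@nullMeans) != object@nPerm)
        msg <- c(msg, "nullMeans must have length nPerm")
    if (!object@mode %in% c("regions", "loci"))
        msg <- c(msg, "mode must be 'regions' or 'loci'")
    if (length(msg)) msg else TRUE
})
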