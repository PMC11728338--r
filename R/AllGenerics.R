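#' Accessors for HiCdci classes
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors bin table of a \linkS4class{ContactMatrix}.
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))

#' @describeIn accessors sparse symmetric contact matrix.
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))

#' @describeIn accessors has the matrix been ICE-balanced?
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @describeIn accessors bin width in bp (modal bin width).
#' @export
setGeneric("binResolution", function(x) standardGeneric("binResolution"))

#' @describeIn accessors TAD intervals of a \linkS4class{TADSet}.
#' @export
setGeneric("tads", function(x) standardGeneric("tads"))

#' @describeIn accessors TAD boundary positions (bp, 0-based breakpoints).
#' @export
setGeneric("boundaries", function(x) standardGeneric("boundaries"))

#' @describeIn accessors per-bin DCI scores of a \linkS4class{DCIProfile}.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

setMethod("bins", "ContactMatrix", function(x) x@bins)
setMethod("contacts", "ContactMatrix", function(x) x@counts)
setMethod("isNormalized", "ContactMatrix", function(x) x@normalized)
setMethod("binResolution", "ContactMatrix", function(x) {
    w <- width(x@bins)
    as.integer(names(sort(table(w), decreasing = TRUE))[1L])
})
setMethod("tads", "TADSet", function(x) x@tads)

setMethod("boundaries", "TADSet", function(x) {
    if (!length(x@tads)) return(numeric())
    sort(unique(c(start(x@tads) - 1, end(x@tads))))
})

setMethod("scores", "DCIProfile", function(x) mcols(x@profile)$score)

setMethod("show", "ContactMatrix", function(object) {
    n <- length(object@bins)
    cat("ContactMatrix with", n, "bins on",
        length(unique(as.character(seqnames(object@bins)))),
        "chromosome(s)\n")
    cat("  resolution:", binResolution(object), "bp;",
        "nonzero entries:", length(object@counts@x), "\n")
    cat("  normalized:", object@normalized,
        "; masked bins:", sum(object@masked), "\n")
})

setMethod("show", "TADSet", function(object) {
    cat("TADSet on", object@chrom, "with", length(object@tads),
        "domains (k =", object@kSelected,
        ", quality =", signif(object@quality, 4), ")\n")
})

setMethod("show", "DCIProfile", function(object) {
    s <- scores(object)
    cat("DCIProfile over", length(s), "bins (window half-width",
        object@windowBins, "bins)\n")
    cat("  score range:", signif(min(s), 3), "..", signif(max(s), 3), "\n")
})

setMethod("show", "AssociationResult", function(object) {
    cat("AssociationResult (n =", object@n, ", ranks",
        paste(object@rankFilter, collapse = ","), ")\n")
    cat("  Spearman rho =", signif(object@rho, 4),
        ", p =", signif(object@pSpearman, 4), "\n")
    cat("  observed mean distance =", round(object@observedMeanDistance),
        "bp\n")
    cat("  permutation p =", signif(object@pPerm, 4),
        " (", object@nPerm, "permutations, mode:", object@mode, ")\n")
})
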