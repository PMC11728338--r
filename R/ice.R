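#' ICE (iterative correction) balancing of a contact matrix
#'
#' Iteratively divides each contact entry by the product of its row and column
#' bias estimates until every unmasked bin has (nearly) the same total
#' visibility. Convergence is declared when the coefficient of variation of
#' the unmasked marginal sums drops to \code{tol}. Diagonal entries are
#' excluded from the marginal sums but are rescaled by the square of the bin
#' bias, and bins with zero or very low coverage (marginal below the 2nd
#' percentile of nonzero marginals) are masked out before correction.
#'
#' The zero pattern of the matrix is preserved exactly, and an
#' already-balanced matrix is returned unchanged.
#'
#' @param m an unnormalized \linkS4class{ContactMatrix}.
#' @param maxIter maximum number of correction sweeps.
#' @param tol target coefficient of variation of the marginals.
#' @param maskQuantile mask bins whose marginal falls below this quantile of
#'   the nonzero marginals (default the 2nd percentile).
#' @return a \linkS4class{ContactMatrix} with \code{isNormalized(m) == TRUE},
#'   per-bin bias factors and the low-coverage mask filled in.
#' @examples
#' cfg <- simulationConfig(chromLengths = c(chrS1 = 5e6))
#' m <- simulateMatrix(cfg, seed = 7)$matrix
#' mN <- iceNormalize(m)
#' isNormalized(mN)
#' @export
iceNormalize <- function(m, maxIter = 200L, tol = 1e-5,
                         maskQuantile = 0.02) {
    stopifnot(is(m, "ContactMatrix"))
    if (isNormalized(m))
        warning("matrix is already flagged as normalized; re-balancing")
    W <- methods::as(contacts(m), "generalMatrix")
    n <- nrow(W)
    if (length(W@x) == 0L || all(W@x == 0))
        stop("cannot balance an all-zero contact matrix")

    marg <- Matrix::rowSums(W) - Matrix::diag(W)
    nzcut <- stats::quantile(marg[marg > 0], maskQuantile, names = FALSE)
    masked <- marg == 0 | marg < nzcut
    if (all(masked)) stop("all bins masked; matrix too sparse to balance")
    if (any(masked)) {
        W[masked, ] <- 0
        W[!masked, masked] <- 0
        W <- Matrix::drop0(W)
    }

    bias <- rep(1, n)
    for (it in seq_len(maxIter)) {
        marg <- Matrix::rowSums(W) - Matrix::diag(W)
        act <- !masked & marg > 0
        if (!any(act)) stop("no active bins left during balancing")
        mu <- mean(marg[act])
        cv <- stats::sd(marg[act]) / mu
        if (cv <= tol) break
        ## square-root damping: same fixed points as the undamped iterative
        ## correction, but also converges when the matrix is block-diagonal
        ## (intra-chromosomal only), where the undamped update oscillates
        ## between chromosomes instead of equalizing them
        db <- rep(1, n)
        db[act] <- sqrt(marg[act] / mu)
        Dinv <- Matrix::Diagonal(n, 1 / db)
        W <- Dinv %*% W %*% Dinv
        bias <- bias * db
    }
    bias[masked] <- NA_real_
    newContactMatrix(bins(m), forceSymmetric(methods::as(W, "CsparseMatrix")),
                     normalized = TRUE, bias = bias, masked = masked)
}
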