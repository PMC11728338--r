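#' Configuration of the synthetic Hi-C generator
#'
#' The generator emulates a condition-paired Hi-C experiment: intra-chromosomal
#' contact maps with power-law distance decay, planted TAD blocks with
#' elevated internal contact, planted differential-contact windows in the
#' second condition, Poisson count noise, and expressed retroviral loci whose
#' expression can be made inversely related to their distance from the planted
#' differential windows.
#'
#' Expected counts follow
#' \deqn{\mu(i,j) = A (1+|i-j|)^{-\alpha} (1 + \beta\,[i,j \in same TAD])}
#' and condition B additionally scales entries with both bins inside a
#' differential window by the window's fold factor before Poisson sampling.
#'
#' @param chromLengths named vector of chromosome lengths in bp. Default two
#'   30-Mb synthetic chromosomes (300 bins each at 100 kb).
#' @param resolution bin width in bp.
#' @param decayExponent power-law decay exponent \eqn{\alpha > 0}.
#' @param baseIntensity expected count \eqn{A} at distance 0; the default 500
#'   mimics deep-coverage Hi-C where adjacent 100-kb bins share hundreds of
#'   contacts.
#' @param tadEnrichment intra-TAD enrichment \eqn{\beta \ge 0}.
#' @param tadSizeRange integer (min, max) TAD size in bins; sizes are drawn
#'   uniformly. Default 6--15 bins (0.6--1.5 Mb), the megabase scale of human
#'   TADs.
#' @param dciSpec data.frame with columns chrom, startBin, endBin, fold
#'   describing planted differential windows (bin indices are 1-based within
#'   each chromosome); see [randomDciSpec()].
#' @param noise \code{"poisson"} or \code{"none"} (emit expectations).
#' @param nLoci number of expressed loci to simulate (the study analyzed 19).
#' @param locusEffect \code{"inverse"} (expression decreasing with distance
#'   from the nearest planted window) or \code{"independent"}.
#' @param locusDistanceRange (min, max) of the log-uniform locus-to-window
#'   gap distances (bp) used in \code{"inverse"} mode. The broad default
#'   (10 kb to 5 Mb) makes the most strongly expressed loci proximal to a
#'   differential window while weakly expressed loci sit at megabase
#'   distances comparable to random placement, so that significance is
#'   carried by the top expression ranks.
#' @param effectScale expression scale (normalized counts) of a locus at
#'   distance 0.
#' @param effectHalfDistance distance (bp) at which expected expression halves
#'   relative to distance 0; expression \eqn{\propto d_0/(d+d_0)}.
#' @param exprNoiseSigma sigma of the multiplicative lognormal expression
#'   noise.
#' @param locusWidth locus width in bp (a full-length HML-2 provirus is
#'   roughly 9 kb).
#' @param seed default seed used when an operation is not given one.
#' @return a validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(chromLengths = c(chrS1 = 3e7, chrS2 = 3e7),
                             resolution = 1e5,
                             decayExponent = 1,
                             baseIntensity = 500,
                             tadEnrichment = 1.5,
                             tadSizeRange = c(6L, 15L),
                             dciSpec = NULL,
                             noise = c("poisson", "none"),
                             nLoci = 19L,
                             locusEffect = c("inverse", "independent"),
                             locusDistanceRange = c(1e4, 5e6),
                             effectScale = 1000,
                             effectHalfDistance = 1e5,
                             exprNoiseSigma = 0.3,
                             locusWidth = 9000L,
                             seed = 1L) {
    noise <- match.arg(noise)
    locusEffect <- match.arg(locusEffect)
    stopifnot(length(chromLengths) >= 1, all(chromLengths > 0),
              !is.null(names(chromLengths)),
              resolution > 0, decayExponent > 0, baseIntensity > 0,
              tadEnrichment >= 0, length(tadSizeRange) == 2,
              tadSizeRange[1] >= 2, tadSizeRange[1] <= tadSizeRange[2],
              nLoci >= 1, locusWidth > 0,
              length(locusDistanceRange) == 2, all(locusDistanceRange > 0),
              locusDistanceRange[1] < locusDistanceRange[2])
    if (!is.null(dciSpec)) {
        stopifnot(is.data.frame(dciSpec),
                  all(c("chrom", "startBin", "endBin", "fold") %in%
                      names(dciSpec)))
        if (any(dciSpec$fold <= 0)) stop("dci fold factors must be > 0")
    }
    structure(list(chromLengths = chromLengths, resolution = resolution,
                   decayExponent = decayExponent,
                   baseIntensity = baseIntensity,
                   tadEnrichment = tadEnrichment,
                   tadSizeRange = as.integer(tadSizeRange),
                   dciSpec = dciSpec, noise = noise,
                   nLoci = as.integer(nLoci), locusEffect = locusEffect,
                   locusDistanceRange = locusDistanceRange,
                   effectScale = effectScale,
                   effectHalfDistance = effectHalfDistance,
                   exprNoiseSigma = exprNoiseSigma,
                   locusWidth = as.integer(locusWidth),
                   seed = as.integer(seed)),
              class = "SimulationConfig")
}

#' Uniform genome bins for a chromosome-sizes table
#'
#' @param chromSizes named vector of chromosome lengths (bp).
#' @param resolution bin width in bp.
#' @return a \code{GRanges} of bins with a \code{bin_id} column and
#'   seqlengths set.
#' @export
binsFromSizes <- function(chromSizes, resolution) {
    pieces <- lapply(names(chromSizes), function(ch) {
        L <- chromSizes[[ch]]
        s <- seq(0, L - 1, by = resolution)
        data.frame(chrom = ch, start = s + 1, end = pmin(s + resolution, L))
    })
    df <- do.call(rbind, pieces)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end))
    GenomeInfoDb::seqlengths(gr) <- chromSizes[seqlevels(gr)]
    mcols(gr)$bin_id <- seq_along(gr)
    gr
}

nBinsPerChrom <- function(cfg) {
    vapply(cfg$chromLengths, function(L) as.integer(ceiling(L / cfg$resolution)),
           integer(1))
}

## sample a complete tiling of `nbins` bins with TAD sizes uniform in range
sampleTadPartition <- function(nbins, sizeRange) {
    if (nbins < sizeRange[1])
        stop("chromosome of ", nbins,
             " bins is shorter than the minimum TAD size (",
             sizeRange[1], " bins)")
    sizes <- integer()
    tot <- 0L
    while (tot < nbins) {
        s <- sample(seq(sizeRange[1], sizeRange[2]), 1L)
        if (nbins - tot - s < sizeRange[1]) s <- nbins - tot
        sizes <- c(sizes, s)
        tot <- tot + s
    }
    sizes
}

tadSetFromSizes <- function(chrom, sizes, resolution, chromLen) {
    ends <- cumsum(sizes)
    starts <- c(0L, ends[-length(ends)])
    gr <- GRanges(chrom, IRanges(starts * resolution + 1,
                                 pmin(ends * resolution, chromLen)))
    mcols(gr)$quality <- NA_real_
    new("TADSet", chrom = chrom, tads = gr, kSelected = NA_integer_,
        quality = NA_real_, seed = NA_integer_)
}

## expected intra-chromosomal contact map for one chromosome
chromExpectation <- function(cfg, labels) {
    n <- length(labels)
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    same <- outer(labels, labels, "==")
    cfg$baseIntensity * (1 + d)^(-cfg$decayExponent) *
        (1 + cfg$tadEnrichment * same)
}

## Poisson-sample a symmetric count matrix from its expectation
drawSymmetric <- function(mu, noise) {
    if (noise == "none") return(mu)
    n <- nrow(mu)
    m <- matrix(0, n, n)
    ut <- upper.tri(m, diag = TRUE)
    m[ut] <- stats::rpois(sum(ut), mu[ut])
    m + t(m) - diag(diag(m))
}

assembleContactMatrix <- function(cfg, chromMats) {
    bgr <- binsFromSizes(cfg$chromLengths, cfg$resolution)
    blocks <- lapply(chromMats, function(m) {
        methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
    })
    cm <- Matrix::bdiag(blocks)
    newContactMatrix(bgr, forceSymmetric(methods::as(cm, "CsparseMatrix")))
}

#' Planted differential windows as genomic regions
#'
#' Converts the \code{dciSpec} of a configuration (bin windows) to bp
#' intervals, e.g. to use the planted windows as the region set of a
#' proximity analysis without simulating matrices.
#'
#' @param cfg a [simulationConfig()] with a non-empty \code{dciSpec}.
#' @return \code{GRanges} with \code{name} and \code{fold} columns.
#' @export
dciSpecRegions <- function(cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    validateDciSpec(cfg)
    dciSpecToGRanges(cfg)
}

dciSpecToGRanges <- function(cfg) {
    sp <- cfg$dciSpec
    if (is.null(sp) || !nrow(sp)) return(GRanges())
    res <- cfg$resolution
    gr <- GRanges(sp$chrom,
                  IRanges((sp$startBin - 1) * res + 1,
                          pmin(sp$endBin * res,
                               cfg$chromLengths[as.character(sp$chrom)])))
    mcols(gr)$name <- paste0("dci", seq_along(gr))
    mcols(gr)$fold <- sp$fold
    gr
}

validateDciSpec <- function(cfg) {
    sp <- cfg$dciSpec
    if (is.null(sp) || !nrow(sp))
        stop("dciSpec must contain at least one differential window")
    nb <- nBinsPerChrom(cfg)
    for (r in seq_len(nrow(sp))) {
        ch <- as.character(sp$chrom[r])
        if (!ch %in% names(nb))
            stop("dci window on unknown chromosome '", ch, "'")
        if (sp$startBin[r] < 1 || sp$endBin[r] > nb[[ch]] ||
            sp$startBin[r] > sp$endBin[r])
            stop("dci window ", r, " lies outside chromosome '", ch, "'")
    }
    for (ch in unique(as.character(sp$chrom))) {
        s <- sp[sp$chrom == ch, , drop = FALSE]
        s <- s[order(s$startBin), , drop = FALSE]
        if (nrow(s) > 1 && any(s$startBin[-1] <= s$endBin[-nrow(s)]))
            stop("overlapping dci windows on chromosome '", ch, "'")
    }
    invisible(TRUE)
}

#' Simulate one Hi-C contact matrix with planted TADs
#'
#' @param cfg a [simulationConfig()].
#' @param seed integer seed; together with \code{cfg} it fully determines the
#'   output.
#' @param truth optionally reuse the planted ground truth (TAD partition) of a
#'   previous call, so that replicates share structure but not noise.
#' @return a list with elements \code{matrix} (a
#'   \linkS4class{ContactMatrix}) and \code{truth} (list with \code{tads}, a
#'   named list of \linkS4class{TADSet}; \code{dcis}, a \code{GRanges}).
#' @export
simulateMatrix <- function(cfg, seed = cfg$seed, truth = NULL) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    withr::with_seed(as.integer(seed), {
        if (is.null(truth)) truth <- drawGroundTruth(cfg)
        labels <- truthLabels(cfg, truth)
        mats <- lapply(names(cfg$chromLengths), function(ch)
            drawSymmetric(chromExpectation(cfg, labels[[ch]]), cfg$noise))
        names(mats) <- names(cfg$chromLengths)
        list(matrix = assembleContactMatrix(cfg, mats), truth = truth)
    })
}

## draw the planted structures (TAD partition + dci windows as configured)
drawGroundTruth <- function(cfg) {
    nb <- nBinsPerChrom(cfg)
    tadsets <- lapply(names(nb), function(ch) {
        sizes <- sampleTadPartition(nb[[ch]], cfg$tadSizeRange)
        tadSetFromSizes(ch, sizes, cfg$resolution, cfg$chromLengths[[ch]])
    })
    names(tadsets) <- names(nb)
    list(tads = tadsets, dcis = dciSpecToGRanges(cfg), loci = NULL)
}

## per-bin TAD labels implied by a ground-truth partition
truthLabels <- function(cfg, truth) {
    nb <- nBinsPerChrom(cfg)
    out <- lapply(names(nb), function(ch) {
        sizes <- as.integer(ceiling(width(tads(truth$tads[[ch]])) /
                                    cfg$resolution))
        lab <- rep(seq_along(sizes), sizes)
        stopifnot(length(lab) == nb[[ch]])
        lab
    })
    names(out) <- names(nb)
    out
}

#' Simulate a condition pair with planted differential windows
#'
#' Condition A follows [simulateMatrix()]; condition B has identical
#' expectation except that entries with both bins inside a \code{dciSpec}
#' window are scaled by the window's fold factor before Poisson sampling.
#'
#' @inheritParams simulateMatrix
#' @return list with \code{matrixA}, \code{matrixB} and \code{truth} (whose
#'   \code{dcis} records the planted windows).
#' @export
simulateConditionPair <- function(cfg, seed = cfg$seed, truth = NULL) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    validateDciSpec(cfg)
    withr::with_seed(as.integer(seed), {
        if (is.null(truth)) truth <- drawGroundTruth(cfg)
        labels <- truthLabels(cfg, truth)
        nb <- nBinsPerChrom(cfg)
        matsA <- list(); matsB <- list()
        for (ch in names(nb)) {
            mu <- chromExpectation(cfg, labels[[ch]])
            muB <- mu
            sp <- cfg$dciSpec[as.character(cfg$dciSpec$chrom) == ch, ,
                              drop = FALSE]
            for (r in seq_len(nrow(sp))) {
                w <- seq(sp$startBin[r], sp$endBin[r])
                muB[w, w] <- muB[w, w] * sp$fold[r]
            }
            matsA[[ch]] <- drawSymmetric(mu, cfg$noise)
            matsB[[ch]] <- drawSymmetric(muB, cfg$noise)
        }
        list(matrixA = assembleContactMatrix(cfg, matsA),
             matrixB = assembleContactMatrix(cfg, matsB),
             truth = truth)
    })
}

#' Draw a random specification of differential windows
#'
#' Windows are placed uniformly (chromosome chosen proportionally to its bin
#' count, start bin uniform) and redrawn on overlap.
#'
#' @param cfg a [simulationConfig()].
#' @param n number of windows.
#' @param widthBins window width in bins.
#' @param fold fold factor applied in condition B.
#' @param seed integer seed.
#' @return a \code{dciSpec} data.frame suitable for [simulationConfig()].
#' @export
randomDciSpec <- function(cfg, n = 4L, widthBins = 5L, fold = 2,
                          seed = cfg$seed) {
    nb <- nBinsPerChrom(cfg)
    withr::with_seed(as.integer(seed), {
        placed <- data.frame(chrom = character(), startBin = integer(),
                             endBin = integer(), fold = numeric())
        tries <- 0L
        while (nrow(placed) < n) {
            tries <- tries + 1L
            if (tries > 1000L * n)
                stop("could not place ", n, " non-overlapping windows")
            ch <- sample(names(nb), 1L, prob = nb)
            if (nb[[ch]] < widthBins) next
            s <- sample.int(nb[[ch]] - widthBins + 1L, 1L)
            e <- s + widthBins - 1L
            same <- placed$chrom == ch
            if (any(same & placed$startBin <= e & placed$endBin >= s)) next
            placed <- rbind(placed,
                            data.frame(chrom = ch, startBin = s, endBin = e,
                                       fold = fold))
        }
        placed[order(placed$chrom, placed$startBin), , drop = FALSE]
    })
}

## place intervals of given widths uniformly on the genome:
## chromosome with probability proportional to length, start uniform over the
## valid positions. Returns 0-based starts. Shared by the locus generator and
## the permutation test so that both draw from the same law.
placeUniform <- function(widths, chromSizes, nbad = "error") {
    k <- length(widths)
    ok <- outer(widths, chromSizes, function(w, L) w <= L)
    if (any(rowSums(ok) == 0))
        stop("an interval is longer than every chromosome")
    probs <- matrix(rep(chromSizes, each = k), nrow = k) * ok
    chromIdx <- apply(probs, 1L, function(p) sample.int(length(p), 1L,
                                                        prob = p))
    ch <- names(chromSizes)[chromIdx]
    L <- chromSizes[chromIdx]
    start0 <- floor(stats::runif(k, 0, L - widths + 1))
    start0 <- pmin(start0, L - widths)
    data.frame(chrom = ch, start0 = start0, end0 = start0 + widths,
               stringsAsFactors = FALSE)
}

#' Simulate expressed retroviral loci
#'
#' In \code{"inverse"} mode each locus is placed at an exponential gap
#' distance from a randomly chosen planted differential window and its
#' expected expression decreases with that distance
#' (\eqn{\propto d_0/(d+d_0)}, multiplicative lognormal noise). In
#' \code{"independent"} mode loci are placed uniformly across the genome and
#' expression is drawn independently of position. Expression ranks are
#' quartile ranks (1 = most highly expressed).
#'
#' @param cfg a [simulationConfig()].
#' @param truth ground truth from [simulateConditionPair()] (needs
#'   \code{truth$dcis} in \code{"inverse"} mode).
#' @param seed integer seed.
#' @return a \code{GRanges} of loci with \code{name},
#'   \code{normalized_count} and \code{expression_rank} columns.
#' @export
simulateExpressedLoci <- function(cfg, truth = NULL, seed = cfg$seed) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    if (cfg$nLoci < 3) stop("at least 3 loci are required")
    sizes <- cfg$chromLengths
    if (any(cfg$locusWidth > sizes))
        stop("locusWidth exceeds a chromosome length")
    withr::with_seed(as.integer(seed), {
        n <- cfg$nLoci
        if (cfg$locusEffect == "independent") {
            pl <- placeUniform(rep(cfg$locusWidth, n), sizes)
            expr <- cfg$effectScale *
                exp(stats::rnorm(n, 0, cfg$exprNoiseSigma))
            gr <- GRanges(pl$chrom, IRanges(pl$start0 + 1, pl$end0))
        } else {
            dcis <- truth$dcis
            if (is.null(dcis) || !length(dcis))
                stop("'inverse' mode needs planted differential windows ",
                     "in truth$dcis")
            ch <- character(n); s0 <- numeric(n); dist <- numeric(n)
            for (i in seq_len(n)) {
                placedOk <- FALSE
                for (try in seq_len(1000L)) {
                    r <- dcis[sample.int(length(dcis), 1L)]
                    d <- round(exp(stats::runif(1L,
                                   log(cfg$locusDistanceRange[1]),
                                   log(cfg$locusDistanceRange[2]))))
                    rightSide <- stats::runif(1L) < 0.5
                    rs0 <- start(r) - 1; re0 <- end(r)
                    cand <- if (rightSide) re0 + d
                            else rs0 - d - cfg$locusWidth
                    L <- sizes[[as.character(seqnames(r))]]
                    if (cand >= 0 && cand + cfg$locusWidth <= L) {
                        ch[i] <- as.character(seqnames(r))
                        s0[i] <- cand
                        dist[i] <- d
                        placedOk <- TRUE
                        break
                    }
                }
                if (!placedOk)
                    stop("could not place locus ", i,
                         ": placements exhausted")
            }
            d0 <- cfg$effectHalfDistance
            expr <- cfg$effectScale * d0 / (dist + d0) *
                exp(stats::rnorm(n, 0, cfg$exprNoiseSigma))
            gr <- GRanges(ch, IRanges(s0 + 1, s0 + cfg$locusWidth))
        }
        GenomeInfoDb::seqlevels(gr) <- names(sizes)
        GenomeInfoDb::seqlengths(gr) <- sizes
        mcols(gr)$name <- sprintf("locus%02d", seq_len(n))
        mcols(gr)$normalized_count <- expr
        mcols(gr)$expression_rank <- expressionRanks(expr)
        gr
    })
}
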