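#' Star annotation for p-values
#'
#' Maps a p-value to the significance annotation used in the figure legends:
#' \code{"*"} for 0.01 < p <= 0.05, \code{"**"} for 0.001 < p <= 0.01,
#' \code{"***"} for 0.0001 < p <= 0.001, \code{"****"} for p <= 0.00001 and
#' \code{"NS"} above 0.05. The legend leaves the interval (0.00001, 0.0001]
#' unmapped; such values are annotated \code{"***+"} and reported via a
#' message rather than silently bridged.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return character vector of annotations.
#' @examples
#' starAnnotation(c(0.03, 0.5, 1e-6))
#' @export
starAnnotation <- function(p) {
    out <- character(length(p))
    for (i in seq_along(p)) {
        pi <- p[i]
        out[i] <-
            if (is.na(pi)) NA_character_
            else if (pi <= 0.00001) "****"
            else if (pi <= 0.0001) {
                message("p = ", signif(pi, 3),
                        " falls in the legend's unmapped interval ",
                        "(1e-5, 1e-4]; annotated '***+'")
                "***+"
            }
            else if (pi <= 0.001) "***"
            else if (pi <= 0.01) "**"
            else if (pi <= 0.05) "*"
            else "NS"
    }
    out
}

pooledSizes <- function(tadsetsByRep, chrom) {
    unlist(lapply(tadsetsByRep, function(ts) {
        s <- ts[[chrom]]
        if (is.null(s)) NULL else width(tads(s))
    }))
}

#' Per-chromosome TAD size comparison between conditions
#'
#' Pools TAD sizes (bp) across replicates within each condition and compares
#' the two conditions per chromosome with the two-sided Mann-Whitney U test
#' (normal approximation with tie and continuity correction). Direction is
#' the sign of the median size difference (condition B minus A).
#'
#' @param tadsetsA,tadsetsB list over replicates; each element a named list
#'   of \linkS4class{TADSet} per chromosome.
#' @return data.frame with chrom, nA, nB, U, p_value, direction, stars.
#' @export
tadSizesByChrom <- function(tadsetsA, tadsetsB) {
    chromsA <- sort(unique(unlist(lapply(tadsetsA, names))))
    chromsB <- sort(unique(unlist(lapply(tadsetsB, names))))
    if (!identical(chromsA, chromsB))
        stop("chromosome present in one condition only: ",
             paste(c(setdiff(chromsA, chromsB), setdiff(chromsB, chromsA)),
                   collapse = ", "))
    rows <- lapply(chromsA, function(ch) {
        szA <- pooledSizes(tadsetsA, ch)
        szB <- pooledSizes(tadsetsB, ch)
        wt <- stats::wilcox.test(szB, szA, exact = FALSE, correct = TRUE)
        data.frame(chrom = ch, nA = length(szA), nB = length(szB),
                   U = unname(wt$statistic), p_value = wt$p.value,
                   direction = sign(stats::median(szB) - stats::median(szA)),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    res$stars <- starAnnotation(res$p_value)
    res
}

#' TAD size-class frequencies and per-class condition comparison
#'
#' Size classes follow the published binning: [0.2-1), [1-1.5), [1.5-2),
#' [2-2.5) Mb plus an overflow class (>= 2.5 Mb). Domains below 200 kb are
#' excluded. For each condition and chromosome the fraction of that
#' chromosome's domains (replicates pooled) falling in each class is
#' computed; per class, the per-chromosome fractions of the two conditions
#' are compared with the two-sided Mann-Whitney U test.
#'
#' @param tadsetsA,tadsetsB list over replicates of per-chromosome
#'   \linkS4class{TADSet} lists.
#' @param binEdges strictly increasing class edges in bp.
#' @return list with \code{frequencies} (long data.frame: condition, chrom,
#'   class, fraction) and \code{tests} (per-class data.frame with U, p_value,
#'   direction, stars; p is NA when a group has fewer than 2 observations).
#' @export
sizeBinFrequencies <- function(tadsetsA, tadsetsB,
                               binEdges = c(2e5, 1e6, 1.5e6, 2e6, 2.5e6)) {
    if (is.unsorted(binEdges, strictly = TRUE))
        stop("binEdges must be strictly increasing")
    fmt <- function(x) formatC(x / 1e6, format = "g")
    labs <- c(sprintf("[%s-%s)", fmt(binEdges[-length(binEdges)]),
                      fmt(binEdges[-1])),
              sprintf(">=%s", fmt(binEdges[length(binEdges)])))
    classify <- function(sz) {
        sz <- sz[sz >= binEdges[1]]
        cut(sz, breaks = c(binEdges, Inf), right = FALSE, labels = labs)
    }
    chroms <- sort(unique(unlist(lapply(c(tadsetsA, tadsetsB), names))))
    freqRows <- list()
    for (cond in c("A", "B")) {
        sets <- if (cond == "A") tadsetsA else tadsetsB
        for (ch in chroms) {
            cl <- classify(pooledSizes(sets, ch))
            if (!length(cl)) next
            tab <- table(cl) / length(cl)
            freqRows[[length(freqRows) + 1L]] <-
                data.frame(condition = cond, chrom = ch,
                           class = names(tab), fraction = as.numeric(tab),
                           stringsAsFactors = FALSE)
        }
    }
    freqs <- do.call(rbind, freqRows)
    tests <- lapply(labs, function(lb) {
        fa <- freqs$fraction[freqs$condition == "A" & freqs$class == lb]
        fb <- freqs$fraction[freqs$condition == "B" & freqs$class == lb]
        if (length(fa) < 2L || length(fb) < 2L)
            return(data.frame(class = lb, U = NA_real_, p_value = NA_real_,
                              direction = sign(stats::median(fb) -
                                               stats::median(fa)),
                              stringsAsFactors = FALSE))
        wt <- stats::wilcox.test(fb, fa, exact = FALSE, correct = TRUE)
        data.frame(class = lb, U = unname(wt$statistic),
                   p_value = wt$p.value,
                   direction = sign(stats::median(fb) - stats::median(fa)),
                   stringsAsFactors = FALSE)
    })
    tests <- do.call(rbind, tests)
    tests$stars <- starAnnotation(tests$p_value)
    list(frequencies = freqs, tests = tests)
}
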