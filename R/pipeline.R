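#' Assemble and validate a pipeline configuration
#'
#' @param samples data.frame with columns condition ("A" reference / "B"
#'   comparison), replicate (integer), bins (path), matrix (path) describing
#'   one Hi-C Pro matrix per condition and replicate.
#' @param lociPath path to the expressed-loci TSV (see [readLociTable()]).
#' @param chromSizesPath path to a chrom.sizes file.
#' @param outDir output directory.
#' @param iceMaxIter,iceTol ICE balancing parameters.
#' @param kRange candidate cluster numbers for TAD calling (NULL = automatic).
#' @param minTadBins minimum TAD size in bins.
#' @param dciWindowBins,dciThreshold,dciMinBins,dciDirection DCI parameters.
#' @param consensusMaxDistance boundary-matching distance in bp.
#' @param nPerm permutations for the proximity test (study default 2000).
#' @param permMode permutation mode, \code{"regions"} or \code{"loci"}.
#' @param rankSets rank subsets for [rankSubsetAnalysis()].
#' @param seed master seed; all stage seeds derive from it.
#' @return validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(samples, lociPath, chromSizesPath, outDir,
                           iceMaxIter = 200L, iceTol = 1e-5,
                           kRange = NULL, minTadBins = 2L,
                           dciWindowBins = 5L, dciThreshold = 2,
                           dciMinBins = 2L,
                           dciDirection = c("increased", "decreased"),
                           consensusMaxDistance = 1e5,
                           nPerm = 2000L,
                           permMode = c("regions", "loci"),
                           rankSets = list(ranks1_2 = c(1L, 2L),
                                           ranks1_4 = 1:4),
                           seed = 0L) {
    dciDirection <- match.arg(dciDirection)
    permMode <- match.arg(permMode)
    samples <- as.data.frame(samples)
    need <- c("condition", "replicate", "bins", "matrix")
    if (!all(need %in% names(samples)))
        stop("samples needs columns: ", paste(need, collapse = ", "))
    if (!setequal(unique(samples$condition), c("A", "B")))
        stop("samples must cover conditions 'A' and 'B'")
    reps <- sort(unique(samples$replicate))
    for (r in reps) for (cond in c("A", "B"))
        if (sum(samples$condition == cond & samples$replicate == r) != 1L)
            stop("need exactly one sample per condition per replicate")
    for (p in c(samples$bins, samples$matrix, lociPath, chromSizesPath))
        if (!file.exists(p)) stop("missing input file: ", p)
    structure(list(samples = samples, lociPath = lociPath,
                   chromSizesPath = chromSizesPath, outDir = outDir,
                   iceMaxIter = as.integer(iceMaxIter), iceTol = iceTol,
                   kRange = kRange, minTadBins = as.integer(minTadBins),
                   dciWindowBins = as.integer(dciWindowBins),
                   dciThreshold = dciThreshold,
                   dciMinBins = as.integer(dciMinBins),
                   dciDirection = dciDirection,
                   consensusMaxDistance = consensusMaxDistance,
                   nPerm = as.integer(nPerm), permMode = permMode,
                   rankSets = rankSets, seed = as.integer(seed)),
              class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param path a YAML file with the fields of [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    y$samples <- do.call(rbind, lapply(y$samples, as.data.frame))
    if (!is.null(y$rankSets))
        y$rankSets <- lapply(y$rankSets, as.integer)
    do.call(pipelineConfig, y)
}

stageLog <- function(stage, ...) {
    message("[", stage, "] ", ...)
}

#' Run the full analysis pipeline
#'
#' Executes, with file-based handoffs under \code{cfg$outDir}: ICE balancing
#' of every sample matrix; TAD calling on every balanced matrix; DCI scoring
#' per replicate pair on depth-matched raw matrices; replicate consensus of
#' DCI regions and matching to the comparison condition's TAD boundaries;
#' proximity statistics of the expressed loci against the matched consensus
#' regions (per rank subset, shared permutation null); and TAD
#' size-distribution statistics between conditions. Any stage failure aborts
#' with the stage named; outputs of completed stages are retained.
#'
#' All stage seeds derive from \code{cfg$seed}, so a rerun with the same
#' configuration and inputs reproduces every output file bitwise. The
#' manifest (\code{manifest.json}) records the configuration, package
#' version, seeds and MD5 checksums of all inputs and outputs.
#'
#' @param cfg a [pipelineConfig()].
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(cfg) {
    stopifnot(inherits(cfg, "PipelineConfig"))
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(...) file.path(cfg$outDir, paste0(...))
    withStage <- function(stage, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    chromSizes <- readChromSizes(cfg$chromSizesPath)
    loci <- readLociTable(cfg$lociPath)
    smp <- cfg$samples[order(cfg$samples$condition, cfg$samples$replicate), ]
    reps <- sort(unique(smp$replicate))

    key <- function(cond, rep) paste0(cond, "_rep", rep)
    raw <- list(); iced <- list()
    withStage("ice", {
        for (i in seq_len(nrow(smp))) {
            k <- key(smp$condition[i], smp$replicate[i])
            stageLog("ice", "balancing sample ", k)
            m <- readHicproMatrix(smp$bins[i], smp$matrix[i])
            raw[[k]] <- m
            mN <- iceNormalize(m, maxIter = cfg$iceMaxIter, tol = cfg$iceTol)
            writeHicproMatrix(mN, out(k, "_iced_abs.bed"),
                              out(k, "_iced.matrix"))
            iced[[k]] <- mN
        }
    })

    tadsets <- list()
    withStage("tads", {
        for (k in names(iced)) {
            stageLog("tads", "calling TADs for sample ", k)
            ts <- callBestTads(iced[[k]], kRange = cfg$kRange,
                               minTadBins = cfg$minTadBins, seed = cfg$seed)
            writeTadBed(ts, out(k, "_tads.bed"), out(k, "_boundaries.tsv"))
            tadsets[[k]] <- ts
        }
    })

    dciRegions <- list()
    withStage("dci", {
        for (r in reps) {
            stageLog("dci", "replicate pair ", r)
            p <- dciProfile(raw[[key("A", r)]], raw[[key("B", r)]],
                            windowBins = cfg$dciWindowBins)
            regs <- callDciRegions(p, scoreThreshold = cfg$dciThreshold,
                                   minBins = cfg$dciMinBins,
                                   direction = cfg$dciDirection)
            writeDciTracks(p, regs, out("dci_rep", r, ".bedgraph"),
                           out("dci_rep", r, "_regions.bed"))
            dciRegions[[as.character(r)]] <- regs
        }
    })

    matched <- NULL
    withStage("consensus", {
        cons <- intersectReplicates(dciRegions)
        stageLog("consensus", length(cons), " consensus region(s)")
        tadsB <- lapply(reps, function(r) tadsets[[key("B", r)]])
        matched <- matchToTadBoundaries(cons, tadsB,
                                        maxDistance = cfg$consensusMaxDistance)
        stageLog("consensus", length(matched),
                 " region(s) within ", cfg$consensusMaxDistance,
                 " bp of a TAD boundary in every replicate")
        writeConsensus(cons, out("consensus_dci.bed"),
                       out("consensus_dci.tsv"))
        writeConsensus(matched, out("consensus_dci_matched.bed"),
                       out("consensus_dci_matched.tsv"))
    })

    assoc <- NULL
    withStage("proximity", {
        if (!length(matched))
            stop("no consensus region matched a TAD boundary")
        ## only loci that can be paired with a same-chromosome region enter
        ## the statistics (the published analysis likewise restricts to loci
        ## paired with a conserved region)
        pairable <- as.character(seqnames(loci)) %in%
            unique(as.character(seqnames(matched)))
        if (!all(pairable))
            stageLog("proximity", sum(!pairable),
                     " locus/loci on chromosomes without a matched region",
                     " excluded")
        loci <- loci[pairable]
        if (length(loci) < 4L)
            stop("fewer than 4 pairable loci")
        ld <- nearestDistance(loci, matched)
        writeLocusDistances(ld, out("locus_distances.tsv"))
        assoc <- rankSubsetAnalysis(loci, matched, chromSizes,
                                    rankSets = cfg$rankSets,
                                    nPerm = cfg$nPerm, seed = cfg$seed,
                                    mode = cfg$permMode)
        for (nm in names(assoc)) {
            writeAssociation(assoc[[nm]], out("association_", nm, ".json"))
            stageLog("proximity", nm, ": rho = ",
                     signif(assoc[[nm]]@rho, 4), ", p_perm = ",
                     signif(assoc[[nm]]@pPerm, 4))
        }
    })

    withStage("tadsize", {
        tadsA <- lapply(reps, function(r) tadsets[[key("A", r)]])
        tadsB <- lapply(reps, function(r) tadsets[[key("B", r)]])
        bychrom <- tadSizesByChrom(tadsA, tadsB)
        fwrite(bychrom, out("tad_sizes_by_chrom.tsv"), sep = "\t",
               quote = FALSE)
        fr <- sizeBinFrequencies(tadsA, tadsB)
        fwrite(fr$frequencies, out("tad_size_frequencies.tsv"), sep = "\t",
               quote = FALSE)
        fwrite(fr$tests, out("tad_size_tests.tsv"), sep = "\t",
               quote = FALSE)
    })

    manifest <- buildManifest(cfg)
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    stageLog("done", "manifest written")
    invisible(manifest)
}

## manifest: configuration echo (without the output location), seeds, and
## checksums of inputs and outputs; no wall-clock fields, so that reruns of
## the same configuration are bitwise identical.
buildManifest <- function(cfg) {
    cfgEcho <- cfg[setdiff(names(cfg), "outDir")]
    cfgEcho$samples <- as.list(cfgEcho$samples)
    outs <- sort(setdiff(list.files(cfg$outDir), "manifest.json"))
    outSums <- as.list(tools::md5sum(file.path(cfg$outDir, outs)))
    names(outSums) <- outs
    ins <- sort(unique(c(cfg$samples$bins, cfg$samples$matrix,
                         cfg$lociPath, cfg$chromSizesPath)))
    inSums <- as.list(tools::md5sum(ins))
    names(inSums) <- basename(ins)
    list(tool = "HiCdci",
         version = as.character(utils::packageVersion("HiCdci")),
         config = cfgEcho, seed = cfg$seed,
         input_md5 = inSums, output_md5 = outSums)
}

## dci windows anchored at internal true TAD boundaries, emulating
## differential contacts that form new domain boundaries
boundaryDciSpec <- function(truth, cfg, n, widthBins, fold) {
    res <- cfg$resolution
    cand <- do.call(rbind, lapply(names(truth$tads), function(ch) {
        b <- internalBoundaries(truth$tads[[ch]])
        if (!length(b)) return(NULL)
        data.frame(chrom = ch, boundBin = round(b / res))
    }))
    if (is.null(cand) || nrow(cand) < n)
        stop("not enough internal TAD boundaries to anchor ", n, " windows")
    nb <- nBinsPerChrom(cfg)
    picks <- sample.int(nrow(cand), nrow(cand))
    placed <- data.frame()
    half <- widthBins %/% 2
    for (i in picks) {
        if (nrow(placed) >= n) break
        ch <- cand$chrom[i]
        s <- cand$boundBin[i] - half + 1L
        e <- s + widthBins - 1L
        if (s < 1 || e > nb[[ch]]) next
        same <- placed$chrom == ch
        if (nrow(placed) && any(same & placed$startBin <= e &
                                placed$endBin >= s)) next
        placed <- rbind(placed, data.frame(chrom = ch, startBin = s,
                                           endBin = e, fold = fold))
    }
    if (nrow(placed) < n)
        stop("could not anchor ", n, " non-overlapping windows")
    placed[order(placed$chrom, placed$startBin), ]
}

#' Simulate a complete condition-paired file bundle
#'
#' Writes, under \code{dir}: one Hi-C Pro matrix per condition and replicate
#' (replicates share the planted ground truth but have independent Poisson
#' noise), the expressed-loci TSV, the chrom.sizes file, ground-truth BEDs
#' (planted TADs and differential windows) and a ready-to-run pipeline
#' configuration \code{config.yaml}. Differential windows are anchored at
#' planted TAD boundaries (\code{anchor = "boundary"}), emulating newly
#' formed domain boundaries, or placed uniformly (\code{anchor = "random"}).
#'
#' @param cfg a [simulationConfig()]; its \code{dciSpec} is ignored in favour
#'   of \code{nWindows} freshly drawn windows.
#' @param dir output directory.
#' @param replicates number of replicate pairs (the study used 3).
#' @param nWindows,widthBins,fold differential-window parameters.
#' @param anchor window placement rule.
#' @param nPerm permutations recorded in the generated configuration.
#' @param seed master seed.
#' @return invisibly, a list with the truth, the generated config path and
#'   the file paths.
#' @export
simulateBundle <- function(cfg, dir, replicates = 3L, nWindows = 4L,
                           widthBins = 5L, fold = 2,
                           anchor = c("boundary", "random"),
                           nPerm = 2000L, seed = cfg$seed) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    anchor <- match.arg(anchor)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    truth <- withr::with_seed(as.integer(seed), drawGroundTruth(cfg))
    spec <- if (anchor == "boundary")
        withr::with_seed(as.integer(seed) + 1L,
                         boundaryDciSpec(truth, cfg, nWindows, widthBins,
                                         fold))
    else randomDciSpec(cfg, nWindows, widthBins, fold,
                       seed = as.integer(seed) + 1L)
    cfg$dciSpec <- spec
    truth$dcis <- dciSpecToGRanges(cfg)

    samples <- list()
    for (r in seq_len(replicates)) {
        pair <- simulateConditionPair(cfg, seed = as.integer(seed) + 10L * r,
                                      truth = truth)
        for (cond in c("A", "B")) {
            m <- if (cond == "A") pair$matrixA else pair$matrixB
            bp <- file.path(dir, sprintf("%s_rep%d_abs.bed", cond, r))
            mp <- file.path(dir, sprintf("%s_rep%d.matrix", cond, r))
            writeHicproMatrix(m, bp, mp)
            samples[[length(samples) + 1L]] <-
                list(condition = cond, replicate = r, bins = bp, matrix = mp)
        }
    }
    loci <- simulateExpressedLoci(cfg, truth,
                                  seed = as.integer(seed) + 500L)
    truth$loci <- loci
    lociPath <- file.path(dir, "loci.tsv")
    writeLociTable(loci, lociPath)
    sizesPath <- file.path(dir, "chrom.sizes")
    writeChromSizes(cfg$chromLengths, sizesPath)

    trueTads <- suppressWarnings(do.call(c, unname(lapply(truth$tads, tads))))
    writeBed(trueTads, file.path(dir, "true_tads.bed"))
    writeBed(truth$dcis, file.path(dir, "true_dcis.bed"))

    yamlPath <- file.path(dir, "config.yaml")
    yaml::write_yaml(list(samples = samples, lociPath = lociPath,
                          chromSizesPath = sizesPath,
                          outDir = file.path(dir, "results"),
                          nPerm = nPerm, seed = as.integer(seed)),
                     yamlPath)
    invisible(list(truth = truth, configPath = yamlPath,
                   lociPath = lociPath, chromSizesPath = sizesPath,
                   sampleTable = do.call(rbind,
                                         lapply(samples, as.data.frame))))
}
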