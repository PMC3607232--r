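# Deterministic synthetic-data generators with planted ground truth.
#
# Every input the pipeline consumes can be generated here: a gene
# annotation on a small genome, per-mark ChIP-seq read sets with planted
# promoter/body enrichment over a uniform background plus a matched
# input, and an expression cohort with a planted log2 shift, MRD classes
# coupled to expression, and censored exponential survival times with a
# planted hazard ratio.  All sampling is driven by a single integer seed;
# a fixed (config, seed) pair reproduces byte-identical outputs.

#' Synthetic-study configuration
#'
#' Bundles every knob of the generators.  Defaults define a compact but
#' realistic study: a 4 Mb two-chromosome genome carrying 60 genes of
#' which 10 are planted triple-mark targets; per-track sequencing at a
#' uniform background of 0.01 fragments/bp with planted windows enriched
#' 40-fold over background (the genome deliberately dwarfs the planted
#' windows because the caller estimates its background expectation from
#' the IP track's own total fragment count, exactly as on a real
#' genome); a cohort of 20 "high" (MLLr-like) and 100 other samples with
#' a planted 1.0 log2 shift on the target set, 2 probes per gene and 1.0
#' log2 units of sample noise; MRD+ prevalence 0.3 with a 0.5 log2
#' expression coupling, exponential survival with baseline hazard
#' 0.1/month, hazard ratio 3 for MRD+ and a 0.2 censoring fraction.
#'
#' @param seed integer seed driving all randomness.
#' @param nGenes number of genes to place.
#' @param chromSizes named vector of chromosome lengths (bp).
#' @param nTargets number of planted target genes.
#' @param geneLengthRange gene length range (bp); lengths are drawn on a
#'   100 bp grid.
#' @param backgroundRate uniform background fragments per bp per track.
#' @param enrichmentFold planted coverage as a multiple of the background
#'   expectation lambda.
#' @param plantedRate fragments-per-bp reference for the planted read
#'   count (planting density = \code{enrichmentFold * plantedRate});
#'   \code{NULL} (default) means \code{backgroundRate}.  Set it
#'   explicitly when simulating with zero background.
#' @param fraglen fragment length (bp) assumed by the enrichment
#'   planting.
#' @param readLength read length (bp) of emitted reads.
#' @param cohort list: \code{nHigh}, \code{nOther}, \code{delta} (planted
#'   log2 shift), \code{probePerGene}, \code{noiseSd} (per-sample log2
#'   noise), \code{probeSd} (per-probe noise), \code{highLabel},
#'   \code{otherLabel}.
#' @param outcomes list: \code{baselineHazard}, \code{hazardRatio} (MRD+
#'   vs MRD-), \code{censoringRate} (target censored fraction),
#'   \code{mrdShift} (log2 coupling of MRD+ to target-set expression),
#'   \code{mrdPrevalence}, \code{mrdMissing} (fraction without MRD data).
#' @return a list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(seed = 1L, nGenes = 60L,
                            chromSizes = c(chr1 = 2.5e6, chr2 = 1.5e6),
                            nTargets = 10L,
                            geneLengthRange = c(2000, 6000),
                            backgroundRate = 0.01, enrichmentFold = 40,
                            plantedRate = NULL,
                            fraglen = 170L, readLength = 36L,
                            cohort = list(), outcomes = list()) {
    co <- utils::modifyList(
        list(nHigh = 20L, nOther = 100L, delta = 1.0, probePerGene = 2L,
             noiseSd = 1.0, probeSd = 0.25, highLabel = "MLLr",
             otherLabel = "other"), cohort)
    oc <- utils::modifyList(
        list(baselineHazard = 0.1, hazardRatio = 3, censoringRate = 0.2,
             mrdShift = 0.5, mrdPrevalence = 0.3, mrdMissing = 0.1), outcomes)
    cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                chromSizes = chromSizes, nTargets = as.integer(nTargets),
                geneLengthRange = geneLengthRange,
                backgroundRate = backgroundRate,
                enrichmentFold = enrichmentFold,
                plantedRate = if (is.null(plantedRate)) backgroundRate
                              else plantedRate,
                fraglen = as.integer(fraglen),
                readLength = as.integer(readLength),
                cohort = co, outcomes = oc)
    stopifnot(cfg$nGenes > 0, cfg$nTargets >= 0,
              cfg$nTargets <= cfg$nGenes, all(cfg$chromSizes > 0),
              cfg$backgroundRate >= 0, cfg$enrichmentFold >= 0,
              cfg$fraglen > 0, cfg$readLength > 0)
    structure(cfg, class = "SyntheticConfig")
}

#' @export
print.SyntheticConfig <- function(x, ...) {
    cat("SyntheticConfig: seed=", x$seed, ", ", x$nGenes, " genes (",
        x$nTargets, " planted) on ", sum(x$chromSizes), " bp; bg=",
        x$backgroundRate, "/bp, fold=", x$enrichmentFold, "; cohort ",
        x$cohort$nHigh, "+", x$cohort$nOther, ", delta=", x$cohort$delta,
        "; HR=", x$outcomes$hazardRatio, "\n", sep = "")
    invisible(x)
}

#' Generate a synthetic gene annotation
#'
#' Places \code{nGenes} non-nested genes of random strand and length
#' (100 bp grid) left to right across the chromosomes, with inter-gene
#' gaps drawn from [4200, 6000] bp so that promoter windows (+/- 2 kb) of
#' distinct genes can never overlap.  Gene ids are \code{g001}...; symbols
#' \code{GENE001}....  The planted target set is a random sample of
#' \code{nTargets} genes.  Fully deterministic per seed.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with \code{genes} (a \code{GRanges} with \code{gene_id},
#'   \code{symbol}), \code{chromSizes}, and \code{truth} (a
#'   \code{SyntheticTruth} holding the planted target ids/symbols).
#' @export
makeGenome <- function(config = syntheticConfig()) {
    set.seed(config$seed)
    margin <- 3000
    lens <- sample(seq(config$geneLengthRange[1], config$geneLengthRange[2],
                       by = 100), config$nGenes, replace = TRUE)
    strands <- sample(c("+", "-"), config$nGenes, replace = TRUE)
    gaps <- sample(4200:6000, config$nGenes, replace = TRUE)
    chrom <- character(config$nGenes)
    starts <- numeric(config$nGenes)
    ci <- 1L
    chromNames <- names(config$chromSizes)
    pos <- margin
    for (i in seq_len(config$nGenes)) {
        while (ci <= length(chromNames) &&
               pos + lens[i] + margin > config$chromSizes[[ci]]) {
            ci <- ci + 1L
            pos <- margin
        }
        if (ci > length(chromNames)) {
            need <- sum(lens + gaps) + 2 * margin * length(chromNames)
            stop("genome too small to place ", config$nGenes,
                 " genes; need roughly ", need, " bp")
        }
        chrom[i] <- chromNames[ci]
        starts[i] <- pos
        pos <- pos + lens[i] + gaps[i]
    }
    genes <- GRanges(chrom, IRanges(starts, width = lens), strand = strands,
                     gene_id = sprintf("g%03d", seq_len(config$nGenes)),
                     symbol = sprintf("GENE%03d", seq_len(config$nGenes)))
    planted <- sort(sample(genes$gene_id, config$nTargets))
    truth <- new("SyntheticTruth", plantedTargets = planted,
                 plantedSymbols = genes$symbol[match(planted,
                                                     genes$gene_id)])
    list(genes = genes, chromSizes = config$chromSizes, truth = truth)
}

# draw n background read GRanges uniformly over the genome
.backgroundReads <- function(n, chromSizes, readLength) {
    if (n <= 0) return(GRanges())
    chrom <- sample(names(chromSizes), n, replace = TRUE,
                    prob = chromSizes / sum(chromSizes))
    maxStart <- chromSizes[chrom] - readLength + 1
    starts <- floor(runif(n, 1, maxStart + 1))
    GRanges(chrom, IRanges(starts, width = readLength),
            strand = sample(c("+", "-"), n, replace = TRUE))
}

# plant reads so that fragment coverage across [lo, hi] approaches
# enrichment_fold * lambda: read 5' ends are placed so fragment centers
# fall uniformly in the window
.plantedReads <- function(chrom, lo, hi, n, fraglen, readLength,
                          chromSize) {
    if (n <= 0) return(GRanges())
    centers <- floor(runif(n, lo, hi + 1))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    half <- fraglen %/% 2
    starts <- ifelse(strands == "+", centers - half,
                     centers + half - readLength + 1)
    starts <- pmin(pmax(starts, 1), chromSize - readLength + 1)
    GRanges(chrom, IRanges(starts, width = readLength), strand = strands)
}

#' Generate synthetic ChIP-seq read sets
#'
#' For each mark, emits uniform background reads at
#' \code{backgroundRate} fragments/bp plus, at every planted gene,
#' enough extra reads centred in the mark-appropriate window to reach
#' about \code{enrichmentFold} times the background coverage: promoter
#' marks concentrate reads in the central half of the promoter window,
#' body marks spread them across the whole gene-body window.  A matched
#' input track carries background only.  Deterministic per seed.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param genome result of \code{\link{makeGenome}} (regenerated from
#'   \code{config} when omitted).
#' @param markWhere named character vector mapping mark name to
#'   \code{"promoter"} or \code{"body"}; default the triple-mark rule
#'   (MLL-N and AF4-C at promoters, H3K79Me2 in bodies).
#' @param policy a \code{WindowPolicy}.
#' @return list with \code{reads} (named list of \code{GRanges}, one per
#'   mark), \code{input} (\code{GRanges}), \code{chromSizes},
#'   \code{genes}, and \code{truth} (planted windows added).
#' @export
makeChipseq <- function(config = syntheticConfig(), genome = NULL,
                        markWhere = c("MLL-N" = "promoter",
                                      "AF4-C" = "promoter",
                                      "H3K79Me2" = "body"),
                        policy = windowPolicy()) {
    if (is.null(genome)) genome <- makeGenome(config)
    set.seed(config$seed + 1000L)
    genes <- genome$genes
    chromSizes <- genome$chromSizes
    planted <- genome$truth@plantedTargets
    idx <- match(planted, genes$gene_id)
    nBg <- round(config$backgroundRate * sum(chromSizes))
    reads <- list()
    windows <- list()
    for (mk in names(markWhere)) {
        win <- switch(markWhere[[mk]],
            promoter = {
                w <- promoterWindows(genes[idx], policy)
                # concentrate in the central half so summit coverage
                # reaches the planted fold
                resize(w, width = pmax(1L, floor(width(w) / 2)),
                       fix = "center")
            },
            body = geneBodyWindows(genes[idx], policy),
            stop("unknown window kind '", markWhere[[mk]], "'"))
        nPer <- as.integer(round(config$enrichmentFold *
                                 config$plantedRate * width(win)))
        pl <- lapply(seq_along(win), function(j) {
            chr <- as.character(seqnames(win))[j]
            if (end(win)[j] > chromSizes[[chr]] || start(win)[j] < 1)
                stop("enrichment window of gene ", planted[j],
                     " outside chromosome ", chr)
            .plantedReads(chr, start(win)[j], end(win)[j], nPer[j],
                          config$fraglen, config$readLength,
                          chromSizes[[chr]])
        })
        mkReads <- c(.backgroundReads(nBg, chromSizes, config$readLength),
                     do.call(c, pl))
        reads[[mk]] <- sort(mkReads, ignore.strand = FALSE)
        w <- win
        mcols(w) <- DataFrame(gene_id = planted)
        windows[[mk]] <- w
    }
    inputReads <- sort(.backgroundReads(nBg, chromSizes,
                                        config$readLength))
    truth <- genome$truth
    truth@plantedWindows <- windows
    list(reads = reads, input = inputReads, chromSizes = chromSizes,
         genes = genes, truth = truth)
}

#' Generate a synthetic patient cohort
#'
#' Builds a probe-level log2 expression matrix with planted structure:
#' per-gene baselines ~ Normal(7, 1.5); samples of the high-expression
#' subtype get \code{+delta} on the planted gene set; MRD+ samples get
#' \code{+mrdShift} on the same set; each gene is measured by
#' \code{probePerGene} probes with a fixed probe offset and independent
#' probe noise.  MRD percentages are drawn below 0.01\% for true MRD-
#' samples and log-uniform in [0.01, 5]\% for MRD+; a fraction
#' \code{mrdMissing} of samples lacks MRD data.  Overall and relapse-free
#' survival are exponential with hazard
#' \code{baselineHazard * hazardRatio^(MRD+)} (RFS at 1.5x baseline),
#' censored by an independent exponential calibrated to the target
#' censoring fraction.  Deterministic per seed.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param geneset planted high-expression symbols; default: a random
#'   sample of \code{nTargets} of the cohort's genes.  To tie the cohort
#'   to a simulated genome, pass \code{plantedSymbols(genome$truth)}.
#' @param symbols gene symbols measured by the array; default
#'   \code{GENE001...} up to \code{nGenes}.
#' @return list with \code{cohort} (a \code{CohortExperiment}) and
#'   \code{truth} (a \code{SyntheticTruth} with delta, hazard ratio and
#'   true MRD classes).
#' @export
makeCohort <- function(config = syntheticConfig(), geneset = NULL,
                       symbols = NULL) {
    co <- config$cohort; oc <- config$outcomes
    if (is.null(symbols))
        symbols <- sprintf("GENE%03d", seq_len(config$nGenes))
    if (is.null(geneset)) {
        set.seed(config$seed + 500L)
        geneset <- sort(sample(symbols, config$nTargets))
    }
    stopifnot(all(geneset %in% symbols))
    set.seed(config$seed + 2000L)
    nS <- co$nHigh + co$nOther
    sampleIds <- sprintf("S%03d", seq_len(nS))
    subtype <- c(rep(co$highLabel, co$nHigh), rep(co$otherLabel, co$nOther))
    inSet <- symbols %in% geneset
    mu <- rnorm(length(symbols), mean = 7, sd = 1.5)
    # latent per-sample MRD class (independent of subtype)
    mrdPos <- rbinom(nS, 1L, oc$mrdPrevalence) == 1L
    shift <- outer(inSet, subtype == co$highLabel) * co$delta +
             outer(inSet, mrdPos) * oc$mrdShift
    geneVal <- mu + shift +
        matrix(rnorm(length(symbols) * nS, sd = co$noiseSd),
               length(symbols), nS)
    k <- co$probePerGene
    probeOffset <- rnorm(length(symbols) * k, sd = 0.3)
    exprs <- geneVal[rep(seq_along(symbols), each = k), , drop = FALSE] +
        probeOffset +
        matrix(rnorm(length(symbols) * k * nS, sd = co$probeSd),
               length(symbols) * k, nS)
    probeIds <- sprintf("%s_p%d", rep(symbols, each = k),
                        rep(seq_len(k), length(symbols)))
    rownames(exprs) <- probeIds
    colnames(exprs) <- sampleIds
    probeMap <- data.frame(probe_id = probeIds,
                           symbol = rep(symbols, each = k))
    mrdPercent <- ifelse(mrdPos, 10^runif(nS, log10(0.01), log10(5)),
                         runif(nS, 0, 0.009))
    mrdPercent[runif(nS) < oc$mrdMissing] <- NA
    hazard <- oc$baselineHazard * ifelse(mrdPos, oc$hazardRatio, 1)
    censRate <- oc$baselineHazard * oc$censoringRate /
        max(1 - oc$censoringRate, 1e-9)
    osT <- rexp(nS, hazard); osC <- rexp(nS, censRate)
    rfsT <- rexp(nS, 1.5 * hazard); rfsC <- rexp(nS, 1.5 * censRate)
    ann <- data.frame(sample_id = sampleIds, subtype = subtype,
                      mrd_percent = mrdPercent,
                      os_time = round(pmin(osT, osC), 3),
                      os_event = as.integer(osT <= osC),
                      rfs_time = round(pmin(rfsT, rfsC), 3),
                      rfs_event = as.integer(rfsT <= rfsC))
    cohort <- cohortExperiment(round(exprs, 4), probeMap, ann)
    truth <- new("SyntheticTruth",
                 plantedTargets = geneset, plantedSymbols = geneset,
                 delta = co$delta, hazardRatio = oc$hazardRatio,
                 mrdClass = stats::setNames(
                     ifelse(mrdPos, "MRD+", "MRD-"), sampleIds))
    list(cohort = cohort, truth = truth)
}

#' Precision, recall and F1 of a recovered gene set
#'
#' @param called character vector of called gene ids (or symbols).
#' @param planted character vector of planted ids (same namespace).
#' @return list with \code{tp}, \code{fp}, \code{fn}, \code{precision},
#'   \code{recall}, \code{f1}.
#' @export
recoveryStats <- function(called, planted) {
    called <- unique(called); planted <- unique(planted)
    tp <- length(intersect(called, planted))
    fp <- length(setdiff(called, planted))
    fn <- length(setdiff(planted, called))
    precision <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
    recall <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
        0 else 2 * precision * recall / (precision + recall)
    list(tp = tp, fp = fp, fn = fn, precision = precision,
         recall = recall, f1 = f1)
}

#' Run the full ChIP target-calling pipeline on a synthetic study
#'
#' Generates (or takes) a synthetic ChIP-seq study, calls peaks per mark
#' (deduplicate, extend, pile up, threshold against the matched input)
#' and applies the triple-mark target rule, then scores recovery of the
#' planted target set.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param sim optional result of \code{\link{makeChipseq}}.
#' @param rule a \code{TargetRule} (marks must match the simulated ones).
#' @param peakConfig a \code{PeakCallerConfig}.
#' @param policy a \code{WindowPolicy}.
#' @return list with \code{calls} (the \code{callTargets} table),
#'   \code{peaks} (named list of peak \code{GRanges}), \code{stats}
#'   (from \code{\link{recoveryStats}}), and \code{truth}.
#' @export
recoverPlantedTargets <- function(config = syntheticConfig(), sim = NULL,
                                  rule = targetRule(),
                                  peakConfig = peakCallerConfig(),
                                  policy = windowPolicy()) {
    if (is.null(sim)) sim <- makeChipseq(config, policy = policy)
    inputTrack <- fragmentCoverage(deduplicateReads(sim$input),
                                   peakConfig@fraglen, sim$chromSizes)
    haveInput <- inputTrack@totalFragments > 0L
    peaks <- lapply(sim$reads, function(r)
        callPeaks(fragmentCoverage(deduplicateReads(r),
                                   peakConfig@fraglen, sim$chromSizes),
                  if (haveInput) inputTrack else NULL, peakConfig))
    calls <- callTargets(rule, peaks, sim$genes, policy)
    st <- recoveryStats(targetGenes(calls), sim$truth@plantedTargets)
    list(calls = calls, peaks = peaks, stats = st, truth = sim$truth)
}

#' Write / read the planted truth as JSON
#'
#' Round-trips every planted structure so recovery can be scored from
#' files alone.
#'
#' @param truth a \code{SyntheticTruth}.
#' @param path JSON file path.
#' @export
writeTruthJson <- function(truth, path) {
    win <- lapply(truth@plantedWindows, function(w)
        data.frame(chrom = as.character(seqnames(w)),
                   start = start(w) - 1L, end = end(w),
                   gene_id = w$gene_id))
    obj <- list(planted_targets = truth@plantedTargets,
                planted_symbols = truth@plantedSymbols,
                planted_windows = win,
                delta = truth@delta, hazard_ratio = truth@hazardRatio,
                mrd_class = as.list(truth@mrdClass))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeTruthJson
#' @export
readTruthJson <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    win <- lapply(obj$planted_windows, function(df)
        GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                gene_id = df$gene_id))
    new("SyntheticTruth",
        plantedTargets = as.character(obj$planted_targets),
        plantedSymbols = as.character(obj$planted_symbols),
        plantedWindows = win,
        delta = as.numeric(obj$delta),
        hazardRatio = as.numeric(obj$hazard_ratio),
        mrdClass = unlist(obj$mrd_class))
}
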