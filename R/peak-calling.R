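# Clonal-read collapsing, fragment-extension pileup, and peak calling.
#
# The caller emulates the parameter roles of the fold-threshold family of
# ChIP-seq callers: -t (minimum height in fold over the uniform background
# expectation lambda), -f (minimum IP/input fold), -fraglen (fragment
# extension).  Height is defined transparently as coverage / lambda so the
# whole rule is checkable against a naive per-base oracle.

#' Collapse clonal reads
#'
#' Reads sharing (chromosome, leftmost mapped position, strand) are
#' presumed PCR duplicates and collapsed to a single read.  Output is
#' sorted by (chrom, start, strand) and therefore order-independent.
#'
#' @param reads \code{GRanges} of aligned reads (strand +/-; width = read
#'   length).
#' @return \code{GRanges} with at most one read per (chrom, start, strand).
#' @examples
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 101, 101),
#'                             width = 36), strand = c("+", "+", "-"))
#' length(deduplicateReads(r))  # 2
#' @export
deduplicateReads <- function(reads) {
    if (length(reads) == 0L) return(reads)
    key <- paste(seqnames(reads), start(reads), strand(reads))
    out <- reads[!duplicated(key)]
    out[order(as.character(seqnames(out)), start(out),
              as.character(strand(out)))]
}

#' Extend reads to fragments and pile up coverage
#'
#' Each read is extended to \code{fraglen} bp from its 5' end (plus-strand
#' reads grow rightwards from their start, minus-strand reads leftwards
#' from their end) and contributes +1 coverage over the extended interval,
#' truncated at chromosome bounds (a message reports how many fragments
#' were truncated).  Total coverage mass equals
#' \code{fragments * fraglen} minus the truncated bases.
#'
#' @param reads \code{GRanges} of (deduplicated) reads.
#' @param fraglen fragment extension length in bp.
#' @param chromSizes named numeric vector of chromosome lengths.
#' @return a \code{CoverageTrack}.
#' @examples
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, width = 36),
#'                             strand = "+")
#' tr <- fragmentCoverage(r, 170, c(chr1 = 1e5))
#' sum(sum(tr@coverage))  # 170
#' @export
fragmentCoverage <- function(reads, fraglen = 170, chromSizes) {
    if (is.null(names(chromSizes)) || any(chromSizes <= 0))
        stop("'chromSizes' must be a named vector of positive lengths")
    extra <- setdiff(as.character(unique(seqnames(reads))), names(chromSizes))
    if (length(extra))
        stop("reads on chromosomes absent from chromSizes: ",
             paste(extra, collapse = ", "))
    gr <- GRanges(seqnames(reads), ranges(reads), strand = strand(reads))
    seqlevels(gr) <- names(chromSizes)
    # out-of-bound reads are reported via the truncation message below
    suppressWarnings(seqlengths(gr) <- chromSizes)
    frags <- suppressWarnings(resize(gr, width = fraglen, fix = "start"))
    trimmed <- suppressWarnings(trim(frags))
    nTrunc <- sum(width(trimmed) < fraglen)
    if (nTrunc > 0L)
        message(nTrunc, " fragment(s) truncated at chromosome bounds")
    cov <- coverage(trimmed, width = chromSizes)
    new("CoverageTrack", coverage = cov, totalFragments = length(gr),
        fraglen = fraglen, genomeSize = sum(chromSizes))
}

#' Call peaks from IP (and optional input) coverage
#'
#' A base is above threshold ("hot") iff its IP coverage is at least
#' \code{t} times the expected uniform background
#' \code{lambda = totalFragments * fraglen / genomeSize}, and -- when an
#' input track is supplied -- the library-size-normalized IP/input ratio is
#' at least \code{f}.  Input coverage is floored at its own lambda before
#' the ratio, so empty input regions cannot produce infinite enrichment.
#' Maximal hot runs separated by at most \code{mergeGap} bp are merged;
#' merged runs narrower than \code{minWidth} are dropped.  Each peak
#' carries its summit (the position of maximal IP coverage among its hot
#' bases), \code{height} (summit coverage / lambda) and
#' \code{fold_vs_input} (normalized IP/input ratio at the summit, \code{NA}
#' without input).  With \code{foldScope = "peak"} the input gate is
#' instead applied once per candidate peak at its summit.
#'
#' @param ip \code{CoverageTrack} of the IP sample.
#' @param input optional \code{CoverageTrack} of the matched input.
#' @param config a \code{PeakCallerConfig}.
#' @return sorted, disjoint \code{GRanges} of peaks with metadata columns
#'   \code{summit}, \code{height}, \code{fold_vs_input}.
#' @export
callPeaks <- function(ip, input = NULL, config = peakCallerConfig()) {
    stopifnot(is(ip, "CoverageTrack"), is(config, "PeakCallerConfig"))
    if (ip@totalFragments == 0L)
        stop("IP track has zero fragments")
    if (!is.null(input)) {
        stopifnot(is(input, "CoverageTrack"))
        dif <- c(setdiff(names(ip@coverage), names(input@coverage)),
                 setdiff(names(input@coverage), names(ip@coverage)))
        if (length(dif))
            stop("IP and input chromosome sets differ: ",
                 paste(unique(dif), collapse = ", "))
        if (input@totalFragments == 0L)
            stop("input track has zero fragments")
    }
    lambda <- expectedBackground(ip)
    perPeakGate <- identical(config@foldScope, "peak")
    res <- list()
    for (chr in names(ip@coverage)) {
        covIp <- ip@coverage[[chr]]
        hot <- covIp >= config@t * lambda
        foldRle <- NULL
        if (!is.null(input)) {
            lambdaIn <- expectedBackground(input)
            covIn <- pmax(input@coverage[[chr]], lambdaIn)
            foldRle <- (covIp / ip@totalFragments) /
                       (covIn / input@totalFragments)
            if (!perPeakGate) hot <- hot & (foldRle >= config@f)
        }
        runs <- reduce(IRanges(hot), min.gapwidth = config@mergeGap + 1)
        runs <- runs[width(runs) >= config@minWidth]
        if (length(runs) == 0L) next
        # summit = argmax coverage among gate-passing bases (zero out the
        # rest; hot bases have coverage >= t*lambda > 0 so they always win)
        covMasked <- covIp
        covMasked[!hot] <- 0
        summit <- viewWhichMaxs(Views(covMasked, runs))
        height <- viewMaxs(Views(covMasked, runs)) / lambda
        fold <- if (is.null(foldRle)) rep(NA_real_, length(runs))
                else as.numeric(foldRle[summit])
        keep <- rep(TRUE, length(runs))
        if (perPeakGate && !is.null(foldRle)) keep <- fold >= config@f
        if (!any(keep)) next
        res[[chr]] <- GRanges(chr, runs[keep], strand = "*",
                              summit = summit[keep], height = height[keep],
                              fold_vs_input = fold[keep])
    }
    if (length(res) == 0L) {
        empty <- GRanges()
        mcols(empty) <- DataFrame(summit = integer(0), height = numeric(0),
                                  fold_vs_input = numeric(0))
        return(empty)
    }
    # per-chromosome pieces carry disjoint seqlevels by construction
    out <- suppressWarnings(do.call(c, unname(res)))
    sort(out, ignore.strand = TRUE)
}

#' Convenience: reads to peaks in one call
#'
#' Deduplicates, extends, piles up and calls peaks for an IP read set with
#' an optional matched input read set.
#'
#' @param ipReads,inputReads \code{GRanges} of aligned reads
#'   (\code{inputReads} may be \code{NULL}).
#' @param chromSizes named vector of chromosome lengths.
#' @param config a \code{PeakCallerConfig}.
#' @return \code{GRanges} of peaks as from \code{\link{callPeaks}}.
#' @export
callPeaksFromReads <- function(ipReads, inputReads = NULL, chromSizes,
                               config = peakCallerConfig()) {
    ipTrack <- fragmentCoverage(deduplicateReads(ipReads), config@fraglen,
                                chromSizes)
    inTrack <- if (is.null(inputReads)) NULL
               else fragmentCoverage(deduplicateReads(inputReads),
                                     config@fraglen, chromSizes)
    callPeaks(ipTrack, inTrack, config)
}

#' Read and write BED-format reads and peaks
#'
#' \code{readBedReads} reads aligned reads from a 6-column BED file
#' (0-based half-open; strand in column 6).  \code{writeBedReads} writes
#' them back.  \code{writePeaksBed} emits peaks as BED6+2 (name, score =
#' height, strand ".", then 0-based summit position and fold_vs_input);
#' \code{readPeaksBed} reads that format.  \code{readChromSizes} reads a
#' two-column chrom/size table.
#'
#' @param path file path.
#' @return \code{readBedReads}/\code{readPeaksBed} return \code{GRanges};
#'   \code{readChromSizes} a named numeric vector.
#' @export
readBedReads <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(df) < 6L) stop("read BED needs 6 columns")
    GRanges(df[[1L]], IRanges(df[[2L]] + 1L, df[[3L]]), strand = df[[6L]])
}

#' @param reads \code{GRanges} of reads.
#' @rdname readBedReads
#' @export
writeBedReads <- function(reads, path) {
    df <- data.frame(chrom = as.character(seqnames(reads)),
                     start = start(reads) - 1L, end = end(reads),
                     name = sprintf("read%d", seq_along(reads)),
                     score = 0L, strand = as.character(strand(reads)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @param peaks \code{GRanges} of peaks from \code{\link{callPeaks}}.
#' @rdname readBedReads
#' @export
writePeaksBed <- function(peaks, path) {
    df <- data.frame(chrom = as.character(seqnames(peaks)),
                     start = start(peaks) - 1L, end = end(peaks),
                     name = sprintf("peak%d", seq_along(peaks)),
                     score = round(peaks$height, 3), strand = ".",
                     summit = peaks$summit - 1L,
                     fold = round(peaks$fold_vs_input, 3))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname readBedReads
#' @export
readPeaksBed <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(df) < 8L) stop("peak BED needs 8 columns (BED6+2)")
    GRanges(df[[1L]], IRanges(df[[2L]] + 1L, df[[3L]]), strand = "*",
            summit = df[[7L]] + 1L, height = df[[5L]],
            fold_vs_input = df[[8L]])
}

#' @rdname readBedReads
#' @export
readChromSizes <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}
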