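# Gene models and the strand-aware promoter / gene-body windows.
#
# Gene models are GRanges (1-based, closed; the Bioconductor convention)
# with mcols gene_id and symbol; one range per transcript, several
# transcripts may share a gene_id.  BED/refFlat 0-based half-open
# coordinates are converted at the I/O boundary.

.checkStrand <- function(genes) {
    s <- as.character(strand(genes))
    bad <- !s %in% c("+", "-")
    if (any(bad)) {
        id <- if (!is.null(genes$gene_id)) genes$gene_id[bad][1L]
              else as.character(which(bad)[1L])
        stop("invalid strand '", s[bad][1L], "' for gene '", id,
             "': must be '+' or '-'")
    }
    invisible(TRUE)
}

#' Transcription start and end sites
#'
#' The TSS of a plus-strand transcript is its start coordinate; of a
#' minus-strand transcript its end coordinate.  \code{tes} is the opposite
#' boundary.  Genes with a strand other than \code{+}/\code{-} raise an
#' error naming the offending gene.
#'
#' @param genes a \code{GRanges} of gene models with a \code{gene_id}
#'   metadata column.
#' @return integer vector of 1-based TSS (or TES) positions.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 20000),
#'                              strand = "+", gene_id = "g1")
#' tss(gr)  # 10001
#' @export
tss <- function(genes) {
    .checkStrand(genes)
    ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
}

#' @rdname tss
#' @export
tes <- function(genes) {
    .checkStrand(genes)
    ifelse(as.character(strand(genes)) == "+", end(genes), start(genes))
}

#' Promoter windows
#'
#' The promoter of a transcript extends \code{promoterUp} bp upstream and
#' \code{promoterDown} bp downstream of its TSS (default +/- 2 kb), on the
#' transcript's own strand; the window is clamped at the chromosome start.
#' Window width is \code{promoterUp + promoterDown} whenever no clamping
#' occurs.
#'
#' @param genes \code{GRanges} of gene models (strand must be +/-).
#' @param policy a \code{WindowPolicy}.
#' @return \code{GRanges} of windows, parallel to \code{genes}, carrying
#'   the same metadata columns.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 20000),
#'                             strand = "+", gene_id = "g1")
#' promoterWindows(g)  # chr1:8001-12000
#' @export
promoterWindows <- function(genes, policy = windowPolicy()) {
    .checkStrand(genes)
    plus <- as.character(strand(genes)) == "+"
    t1 <- tss(genes)
    newStart <- ifelse(plus, t1 - policy@promoterUp,
                             t1 - policy@promoterDown + 1)
    newEnd <- ifelse(plus, t1 + policy@promoterDown - 1,
                           t1 + policy@promoterUp)
    out <- genes
    ranges(out) <- IRanges(pmax(1, newStart), pmax(1, newEnd))
    out
}

#' Gene-body windows
#'
#' The gene body extends \code{bodyUp} bp upstream of the TSS to
#' \code{bodyDown} bp downstream of the TES (default -2 kb TSS to +1 kb
#' TES), clamped at the chromosome start.
#'
#' @inheritParams promoterWindows
#' @return \code{GRanges} of windows, parallel to \code{genes}.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 20000),
#'                             strand = "+", gene_id = "g1")
#' geneBodyWindows(g)  # chr1:8001-21000
#' @export
geneBodyWindows <- function(genes, policy = windowPolicy()) {
    .checkStrand(genes)
    plus <- as.character(strand(genes)) == "+"
    newStart <- ifelse(plus, start(genes) - policy@bodyUp,
                             start(genes) - policy@bodyDown)
    newEnd <- ifelse(plus, end(genes) + policy@bodyDown,
                           end(genes) + policy@bodyUp)
    out <- genes
    ranges(out) <- IRanges(pmax(1, newStart), pmax(1, newEnd))
    out
}

#' Read gene models from a refFlat-style table
#'
#' Reads the first six columns of a UCSC refFlat file (geneName, name,
#' chrom, strand, txStart, txEnd; txStart is 0-based) into a \code{GRanges}
#' with \code{gene_id} (the transcript/name column) and \code{symbol}
#' metadata columns.  Extra columns (cds bounds, exon structure) are
#' ignored.  \code{readBedGenes} reads 6-column BED (name used as both id
#' and symbol).
#'
#' @param path file path.
#' @param chromPrefix normalize chromosome names: \code{"keep"} (default),
#'   \code{"add"} (prefix bare names with "chr") or \code{"strip"}.
#' @return \code{GRanges} of gene models.
#' @export
readRefFlat <- function(path, chromPrefix = c("keep", "add", "strip")) {
    chromPrefix <- match.arg(chromPrefix)
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "#")
    if (ncol(df) < 6L)
        stop("refFlat file needs >= 6 columns, got ", ncol(df))
    gr <- GRanges(.normChrom(df[[3L]], chromPrefix),
                  IRanges(df[[5L]] + 1L, df[[6L]]),
                  strand = df[[4L]],
                  gene_id = as.character(df[[2L]]),
                  symbol = as.character(df[[1L]]))
    if (anyDuplicated(gr$gene_id))
        stop("duplicated gene_id in annotation: ",
             gr$gene_id[duplicated(gr$gene_id)][1L])
    gr
}

#' @param genes \code{GRanges} of gene models with \code{gene_id} and
#'   \code{symbol}.
#' @rdname readRefFlat
#' @export
writeRefFlat <- function(genes, path) {
    df <- data.frame(geneName = genes$symbol, name = genes$gene_id,
                     chrom = as.character(seqnames(genes)),
                     strand = as.character(strand(genes)),
                     txStart = start(genes) - 1L, txEnd = end(genes))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname readRefFlat
#' @export
readBedGenes <- function(path, chromPrefix = c("keep", "add", "strip")) {
    chromPrefix <- match.arg(chromPrefix)
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "#")
    if (ncol(df) < 6L) stop("BED gene file needs 6 columns")
    GRanges(.normChrom(df[[1L]], chromPrefix),
            IRanges(df[[2L]] + 1L, df[[3L]]), strand = df[[6L]],
            gene_id = as.character(df[[4L]]),
            symbol = as.character(df[[4L]]))
}

#' Write windows as BED6
#'
#' Emits intervals in BED6 (0-based half-open), name = \code{gene_id},
#' score = 0.
#'
#' @param windows \code{GRanges} with a \code{gene_id} column.
#' @param path output file.
#' @export
writeWindowsBed <- function(windows, path) {
    df <- data.frame(chrom = as.character(seqnames(windows)),
                     start = start(windows) - 1L, end = end(windows),
                     name = windows$gene_id, score = 0L,
                     strand = as.character(strand(windows)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

.normChrom <- function(x, mode = "keep") {
    x <- as.character(x)
    switch(mode,
        keep = x,
        add = ifelse(grepl("^chr", x), x, paste0("chr", x)),
        strip = sub("^chr", "", x))
}
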