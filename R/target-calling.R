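# Multi-mark target-gene classification and cross-cell-line consensus.
#
# A gene is a fusion-protein target when every required promoter mark has
# a peak overlapping the promoter window of at least one of its
# transcripts AND every required gene-body mark has a peak overlapping the
# body window (any-transcript, any >=1 bp overlap).  Target sets from
# different cell lines are intersected at the symbol level.

#' Flag genes hit by a peak set
#'
#' A gene is flagged iff at least one peak overlaps the designated window
#' (promoter or gene body) of at least one of its transcripts; overlap of
#' a single base suffices.  The sweep is the sorted interval-join of
#' \code{findOverlaps}.
#'
#' @param peaks \code{GRanges} of peaks (any metadata ignored).
#' @param genes \code{GRanges} of gene models with \code{gene_id}
#'   metadata; several transcripts may share a \code{gene_id}.
#' @param where \code{"promoter"} or \code{"body"}.
#' @param policy a \code{WindowPolicy}.
#' @return named logical vector over unique \code{gene_id}s.
#' @export
flagGenes <- function(peaks, genes, where = c("promoter", "body"),
                      policy = windowPolicy()) {
    where <- match.arg(where)
    win <- switch(where,
        promoter = promoterWindows(genes, policy),
        body = geneBodyWindows(genes, policy))
    # disjoint seqlevel sets (peaks confined to one chromosome) are fine
    hit <- suppressWarnings(overlapsAny(win, peaks, ignore.strand = TRUE))
    ids <- unique(genes$gene_id)
    flagged <- tapply(hit, factor(genes$gene_id, levels = ids), any)
    stats::setNames(as.logical(flagged), ids)
}

#' Call target genes from per-mark peak sets
#'
#' Applies a \code{TargetRule}: \code{is_target} is the AND over all
#' required promoter-mark flags and body-mark flags.  A single peak that
#' overlaps both windows of a gene counts for both flags (the windows
#' deliberately overlap near the TSS).
#'
#' @param rule a \code{TargetRule}.
#' @param markSets named list of peak \code{GRanges}, one per mark; every
#'   mark named in the rule must be present.
#' @param genes \code{GRanges} of gene models (\code{gene_id},
#'   \code{symbol}).
#' @param policy a \code{WindowPolicy}.
#' @return \code{DataFrame} with one row per gene: \code{gene_id},
#'   \code{symbol}, a \code{promoter_<mark>} column per promoter mark, a
#'   \code{body_<mark>} column per body mark, and \code{is_target}.
#' @export
callTargets <- function(rule, markSets, genes, policy = windowPolicy()) {
    stopifnot(is(rule, "TargetRule"))
    need <- unique(c(rule@promoterMarks, rule@bodyMarks))
    missing <- setdiff(need, names(markSets))
    if (length(missing))
        stop("mark(s) missing from markSets: ",
             paste(missing, collapse = ", "))
    ids <- unique(genes$gene_id)
    sym <- genes$symbol[match(ids, genes$gene_id)]
    out <- DataFrame(gene_id = ids, symbol = sym)
    target <- rep(TRUE, length(ids))
    for (mk in rule@promoterMarks) {
        fl <- flagGenes(markSets[[mk]], genes, "promoter", policy)
        out[[paste0("promoter_", mk)]] <- unname(fl[ids])
        target <- target & fl[ids]
    }
    for (mk in rule@bodyMarks) {
        fl <- flagGenes(markSets[[mk]], genes, "body", policy)
        out[[paste0("body_", mk)]] <- unname(fl[ids])
        target <- target & fl[ids]
    }
    out$is_target <- unname(target)
    out
}

#' @return \code{targetGenes} returns the ids (or symbols) of the genes
#'   called targets in a \code{callTargets} result.
#' @param calls a \code{DataFrame} from \code{\link{callTargets}}.
#' @param use \code{"gene_id"} or \code{"symbol"}.
#' @rdname callTargets
#' @export
targetGenes <- function(calls, use = c("gene_id", "symbol")) {
    use <- match.arg(use)
    as.character(calls[[use]][calls$is_target])
}

#' Normalize gene symbols for set operations
#'
#' Uppercases and strips surrounding whitespace.  Symbol-level matching is
#' lossy for aliases; it is the convention used for cross-cell-line gene
#' lists.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalizeSymbols <- function(x) toupper(trimws(as.character(x)))

#' Consensus (intersection) of two target gene sets
#'
#' Exact intersection of gene identifiers after symbol normalization
#' (uppercase, whitespace-stripped).  Commutative, associative, and a
#' subset of each argument.
#'
#' @param setA,setB character vectors of gene symbols.
#' @return sorted character vector of common genes.
#' @examples
#' consensusGenes(c("A", "B", "C"), c("B", "C", "D"))  # "B" "C"
#' @export
consensusGenes <- function(setA, setB) {
    sort(intersect(unique(normalizeSymbols(setA)),
                   unique(normalizeSymbols(setB))))
}

#' Full Venn partition of gene sets
#'
#' Counts every region of the Venn partition of two or more gene sets.
#' Region signatures are the member set labels joined by \code{"&"} in the
#' input order; counts sum to the size of the union.
#'
#' @param sets named list (>= 2) of character vectors of gene symbols.
#' @return named integer vector of region counts.
#' @examples
#' overlapPartition(list(A = c("x", "y"), B = c("y", "z")))
#' @export
overlapPartition <- function(sets) {
    if (length(sets) < 2L || is.null(names(sets)))
        stop("need a named list of >= 2 sets")
    sets <- lapply(sets, function(s) unique(normalizeSymbols(s)))
    universe <- unique(unlist(sets))
    member <- vapply(sets, function(s) universe %in% s,
                     logical(length(universe)))
    member <- matrix(member, nrow = length(universe),
                     dimnames = list(NULL, names(sets)))
    sig <- apply(member, 1L, function(m) paste(names(sets)[m],
                                               collapse = "&"))
    counts <- table(sig)
    stats::setNames(as.integer(counts), names(counts))
}

#' Read / write plain-text gene lists and target-call tables
#'
#' Gene lists are newline-delimited symbol files; target-call tables are
#' TSV with header (gene_id, symbol, one column per flag, is_target).
#'
#' @param path file path.
#' @return \code{readGeneList} returns a character vector;
#'   \code{readTargetCalls} a \code{DataFrame}.
#' @export
readGeneList <- function(path) {
    x <- readLines(path)
    x[nzchar(trimws(x))]
}

#' @param genes character vector of gene symbols.
#' @rdname readGeneList
#' @export
writeGeneList <- function(genes, path) {
    writeLines(as.character(genes), path)
    invisible(path)
}

#' @param calls \code{DataFrame} from \code{\link{callTargets}}.
#' @rdname readGeneList
#' @export
writeTargetCalls <- function(calls, path) {
    utils::write.table(as.data.frame(calls), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname readGeneList
#' @export
readTargetCalls <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    as(df, "DataFrame")
}
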