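#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import GenomeInfoDb
#' @import SummarizedExperiment
#' @importFrom survival Surv survfit survdiff
#' @importFrom stats rnorm runif rexp rbinom wilcox.test pchisq
#' @importFrom utils read.table write.table
#' @importFrom jsonlite write_json read_json
NULL

#' Promoter and gene-body annotation windows
#'
#' A \code{WindowPolicy} fixes the strand-aware windows used to annotate
#' peaks to genes: the promoter extends \code{promoterUp} bp upstream to
#' \code{promoterDown} bp downstream of the TSS, and the gene body extends
#' \code{bodyUp} bp upstream of the TSS to \code{bodyDown} bp downstream of
#' the TES.  The defaults (2000/2000 and 2000/1000) are the standard
#' promoter +/- 2 kb and body -2 kb TSS to +1 kb TES convention.
#'
#' @slot promoterUp,promoterDown,bodyUp,bodyDown single non-negative numbers
#'   (bp).
#' @export
setClass("WindowPolicy",
    representation(promoterUp = "numeric", promoterDown = "numeric",
                   bodyUp = "numeric", bodyDown = "numeric"),
    prototype(promoterUp = 2000, promoterDown = 2000,
              bodyUp = 2000, bodyDown = 1000))

setValidity("WindowPolicy", function(object) {
    v <- c(object@promoterUp, object@promoterDown, object@bodyUp,
           object@bodyDown)
    if (length(v) != 4L || anyNA(v) || any(v < 0))
        return("all window extents must be single non-negative numbers")
    TRUE
})

#' @param promoterUp,promoterDown,bodyUp,bodyDown window extents in bp.
#' @return \code{windowPolicy} returns a \code{WindowPolicy} object.
#' @rdname WindowPolicy-class
#' @examples
#' windowPolicy()
#' @export
windowPolicy <- function(promoterUp = 2000, promoterDown = 2000,
                         bodyUp = 2000, bodyDown = 1000) {
    new("WindowPolicy", promoterUp = promoterUp, promoterDown = promoterDown,
        bodyUp = bodyUp, bodyDown = bodyDown)
}

setMethod("show", "WindowPolicy", function(object) {
    cat("WindowPolicy: promoter [-", object@promoterUp, ", +",
        object@promoterDown, "] around TSS; body [TSS - ", object@bodyUp,
        ", TES + ", object@bodyDown, "]\n", sep = "")
})

#' Peak-caller configuration
#'
#' Parameters of the fold-over-background peak caller: \code{t} is the
#' minimum peak height in fold-over-expected-background units, \code{f}
#' the minimum IP/input fold enrichment, and \code{fraglen} the fragment
#' extension length in bp.  The defaults (t = 15, f = 2, fraglen = 170)
#' reproduce the parameterization used throughout this pipeline.
#' \code{mergeGap} is the largest gap (bp) between above-threshold runs
#' merged into one peak (default \code{fraglen}); runs narrower than
#' \code{minWidth} are dropped.  \code{foldScope} selects whether the
#' IP/input gate is applied per base ("base", default) or per peak at the
#' summit ("peak").
#'
#' @slot t,f,fraglen,mergeGap,minWidth single numbers, see Description.
#' @slot foldScope "base" or "peak".
#' @export
setClass("PeakCallerConfig",
    representation(t = "numeric", f = "numeric", fraglen = "numeric",
                   mergeGap = "numeric", minWidth = "numeric",
                   foldScope = "character"),
    prototype(t = 15, f = 2, fraglen = 170, mergeGap = 170, minWidth = 1,
              foldScope = "base"))

setValidity("PeakCallerConfig", function(object) {
    if (object@t <= 0) return("'t' must be > 0")
    if (object@f < 1) return("'f' must be >= 1")
    if (object@fraglen <= 0) return("'fraglen' must be > 0")
    if (object@mergeGap < 0) return("'mergeGap' must be >= 0")
    if (object@minWidth < 1) return("'minWidth' must be >= 1")
    if (!object@foldScope %in% c("base", "peak"))
        return("'foldScope' must be \"base\" or \"peak\"")
    TRUE
})

#' @param t,f,fraglen,mergeGap,minWidth,foldScope see the class description.
#' @return \code{peakCallerConfig} returns a \code{PeakCallerConfig} object.
#' @rdname PeakCallerConfig-class
#' @examples
#' peakCallerConfig(t = 15, f = 2, fraglen = 170)
#' @export
peakCallerConfig <- function(t = 15, f = 2, fraglen = 170,
                             mergeGap = fraglen, minWidth = 1,
                             foldScope = c("base", "peak")) {
    new("PeakCallerConfig", t = t, f = f, fraglen = fraglen,
        mergeGap = mergeGap, minWidth = minWidth,
        foldScope = match.arg(foldScope))
}

setMethod("show", "PeakCallerConfig", function(object) {
    cat("PeakCallerConfig: t=", object@t, " f=", object@f, " fraglen=",
        object@fraglen, " mergeGap=", object@mergeGap, " minWidth=",
        object@minWidth, " foldScope=", object@foldScope, "\n", sep = "")
})

#' Per-base fragment coverage with its background expectation
#'
#' Holds the per-chromosome fragment pileup of one ChIP (or input) track
#' together with the bookkeeping needed for background normalization: the
#' number of (deduplicated) fragments, the extension length, and the
#' effective genome size.  The expected per-base background coverage is
#' \code{lambda = totalFragments * fraglen / genomeSize}.
#'
#' @slot coverage an \code{RleList} of per-base fragment counts.
#' @slot totalFragments number of fragments piled up.
#' @slot fraglen fragment extension length (bp).
#' @slot genomeSize effective genome size (bp).
#' @export
setClass("CoverageTrack",
    representation(coverage = "ANY", totalFragments = "numeric",
                   fraglen = "numeric", genomeSize = "numeric"))

setValidity("CoverageTrack", function(object) {
    if (object@totalFragments < 0) return("negative fragment count")
    if (object@fraglen <= 0) return("'fraglen' must be > 0")
    if (object@genomeSize <= 0) return("'genomeSize' must be > 0")
    TRUE
})

#' @param object a \code{CoverageTrack}.
#' @rdname CoverageTrack-class
setMethod("show", "CoverageTrack", function(object) {
    cat("CoverageTrack: ", object@totalFragments, " fragments x ",
        object@fraglen, " bp over ", object@genomeSize, " bp (",
        length(object@coverage), " chromosomes); lambda = ",
        signif(expectedBackground(object), 4), "\n", sep = "")
})

#' @return \code{expectedBackground} returns the expected per-base
#'   background coverage lambda of a track.
#' @rdname CoverageTrack-class
#' @export
expectedBackground <- function(object) {
    stopifnot(is(object, "CoverageTrack"))
    object@totalFragments * object@fraglen / object@genomeSize
}

#' Multi-mark target-gene rule
#'
#' A gene is called a target when every mark in \code{promoterMarks} has a
#' peak overlapping the gene's promoter window and every mark in
#' \code{bodyMarks} has a peak overlapping its gene-body window.  The
#' default rule (MLL-N and AF4-C at the promoter, H3K79Me2 in the body) is
#' the triple-evidence definition of a fusion-protein target gene.
#'
#' @slot promoterMarks,bodyMarks character vectors of mark names.
#' @export
setClass("TargetRule",
    representation(promoterMarks = "character", bodyMarks = "character"),
    prototype(promoterMarks = c("MLL-N", "AF4-C"), bodyMarks = "H3K79Me2"))

setValidity("TargetRule", function(object) {
    if (length(object@promoterMarks) + length(object@bodyMarks) < 1L)
        return("at least one mark must be required")
    TRUE
})

#' @param promoterMarks,bodyMarks character vectors of mark names.
#' @return \code{targetRule} returns a \code{TargetRule} object.
#' @rdname TargetRule-class
#' @examples
#' targetRule(promoterMarks = c("MLL-N", "AF4-C"), bodyMarks = "H3K79Me2")
#' @export
targetRule <- function(promoterMarks = c("MLL-N", "AF4-C"),
                       bodyMarks = "H3K79Me2") {
    new("TargetRule", promoterMarks = promoterMarks, bodyMarks = bodyMarks)
}

setMethod("show", "TargetRule", function(object) {
    cat("TargetRule: promoter {", paste(object@promoterMarks, collapse = ", "),
        "} AND body {", paste(object@bodyMarks, collapse = ", "), "}\n",
        sep = "")
})

#' Patient expression cohort container
#'
#' A \code{CohortExperiment} extends \code{SummarizedExperiment} to hold a
#' probe-level log2 expression matrix (assay \code{"log2"}), the
#' probe-to-gene map (\code{rowData(x)$symbol}, \code{NA} for unmapped
#' probes), and per-sample clinical annotations in \code{colData}:
#' \code{subtype}, \code{mrd_percent} and optional \code{os_time},
#' \code{os_event}, \code{rfs_time}, \code{rfs_event}.
#'
#' Missing expression values are disallowed: matrices are assumed complete
#' after upstream normalization, and explicit failure beats silent
#' imputation.  Probes mapping to more than one gene are dropped at
#' construction with a warning.
#'
#' @export
setClass("CohortExperiment", contains = "SummarizedExperiment")

setValidity("CohortExperiment", function(object) {
    if (!"log2" %in% SummarizedExperiment::assayNames(object))
        return("assay 'log2' is required")
    m <- SummarizedExperiment::assay(object, "log2")
    if (anyNA(m) || any(!is.finite(m)))
        return("expression values must be finite (no NA/Inf)")
    if (!"symbol" %in% colnames(SummarizedExperiment::rowData(object)))
        return("rowData must carry a 'symbol' column (probe -> gene map)")
    if (!"subtype" %in% colnames(SummarizedExperiment::colData(object)))
        return("colData must carry a 'subtype' column")
    TRUE
})

#' Construct a CohortExperiment
#'
#' @param exprs numeric matrix of log2 expression values, probes in rows
#'   (rownames are probe ids), samples in columns.
#' @param probeMap data.frame with columns \code{probe_id} and
#'   \code{symbol}.  Probes of \code{exprs} absent from the map are kept
#'   with \code{symbol = NA} (flagged unmapped); probes mapping to several
#'   distinct genes are dropped with a warning.
#' @param annotations data.frame with a \code{sample_id} column matching
#'   \code{colnames(exprs)} plus \code{subtype} and the optional clinical
#'   columns (\code{mrd_percent}, \code{os_time}, \code{os_event},
#'   \code{rfs_time}, \code{rfs_event}).
#' @return a \code{CohortExperiment}.
#' @examples
#' m <- matrix(rnorm(6, 7), 2, 3,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
#' pm <- data.frame(probe_id = c("p1", "p2"), symbol = c("TP53", "TP53"))
#' ann <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                   subtype = c("MLLr", "other", "other"))
#' cohortExperiment(m, pm, ann)
#' @export
cohortExperiment <- function(exprs, probeMap, annotations) {
    exprs <- as.matrix(exprs)
    if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
        stop("expression matrix must have probe rownames and sample colnames")
    if (anyNA(exprs) || any(!is.finite(exprs)))
        stop("expression matrix contains missing or non-finite values; ",
             "matrices must be complete after normalization")
    stopifnot(all(c("probe_id", "symbol") %in% colnames(probeMap)))
    pm <- unique(probeMap[, c("probe_id", "symbol")])
    ngene <- table(pm$probe_id)
    multi <- names(ngene)[ngene > 1L]
    if (length(multi)) {
        warning(length(multi), " probe(s) mapping to multiple genes dropped")
        pm <- pm[!pm$probe_id %in% multi, ]
    }
    symbol <- pm$symbol[match(rownames(exprs), pm$probe_id)]
    if (!"sample_id" %in% colnames(annotations))
        stop("annotations must have a 'sample_id' column")
    idx <- match(colnames(exprs), annotations$sample_id)
    if (anyNA(idx))
        stop("samples missing from annotations: ",
             paste(colnames(exprs)[is.na(idx)], collapse = ", "))
    cd <- annotations[idx, setdiff(colnames(annotations), "sample_id"),
                      drop = FALSE]
    rownames(cd) <- colnames(exprs)
    if (!"subtype" %in% colnames(cd)) stop("annotations need 'subtype'")
    se <- SummarizedExperiment(
        assays = list(log2 = exprs),
        rowData = DataFrame(symbol = symbol, row.names = rownames(exprs)),
        colData = as(cd, "DataFrame"))
    new("CohortExperiment", se)
}

setMethod("show", "CohortExperiment", function(object) {
    callNextMethod()
    sym <- SummarizedExperiment::rowData(object)$symbol
    cat("probes mapped: ", sum(!is.na(sym)), "/", length(sym), " (",
        length(unique(sym[!is.na(sym)])), " genes); subtypes: ",
        paste(levels(factor(object$subtype)), collapse = ", "), "\n",
        sep = "")
})

#' Planted ground truth of a synthetic data set
#'
#' Records everything the synthetic generators planted so that recovery can
#' be scored: the planted target gene ids and symbols, the per-mark planted
#' enrichment windows, the planted log2 expression shift and hazard ratio,
#' and the per-sample true MRD class.
#'
#' @slot plantedTargets character, planted target gene ids.
#' @slot plantedSymbols character, the matching gene symbols.
#' @slot plantedWindows named list of \code{GRanges}, one per mark.
#' @slot delta planted log2 expression shift.
#' @slot hazardRatio planted MRD+ vs MRD- hazard ratio.
#' @slot mrdClass named character of true MRD classes per sample.
#' @export
setClass("SyntheticTruth",
    representation(plantedTargets = "character", plantedSymbols = "character",
                   plantedWindows = "list", delta = "numeric",
                   hazardRatio = "numeric", mrdClass = "character"),
    prototype(plantedTargets = character(), plantedSymbols = character(),
              plantedWindows = list(), delta = numeric(),
              hazardRatio = numeric(), mrdClass = character()))

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth: ", length(object@plantedTargets),
        " planted targets", sep = "")
    if (length(object@plantedWindows))
        cat("; marks: ", paste(names(object@plantedWindows), collapse = ", "),
            sep = "")
    if (length(object@delta)) cat("; delta=", object@delta, sep = "")
    if (length(object@hazardRatio))
        cat("; HR=", object@hazardRatio, sep = "")
    cat("\n")
})

#' @return \code{plantedTargets} returns the planted target gene ids;
#'   \code{plantedSymbols} the matching symbols.
#' @param truth a \code{SyntheticTruth}.
#' @rdname SyntheticTruth-class
#' @export
plantedTargets <- function(truth) truth@plantedTargets

#' @rdname SyntheticTruth-class
#' @export
plantedSymbols <- function(truth) truth@plantedSymbols
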