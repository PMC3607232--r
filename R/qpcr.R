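# Closed-form qPCR arithmetic: ChIP percent-of-input and delta-CT
# relative expression with its two normalization conventions.

.checkCt <- function(...) {
    for (v in list(...))
        if (anyNA(v) || any(!is.finite(v)))
            stop("CT values must be finite")
    invisible(TRUE)
}

#' ChIP signal as percent of total input
#'
#' The amount of DNA co-precipitated by an antibody, expressed as a
#' percentage of the total chromatin:
#' \code{2^(ctInput - ctIp) * inputFraction * 100}.  With the standard
#' 5\% input aliquot, equal CTs give exactly 5\%; each cycle of
#' difference doubles (or halves) the signal.
#'
#' @param ctInput CT of the input (reference) sample.
#' @param ctIp CT of the chromatin IP sample.
#' @param inputFraction fraction of total chromatin in the input aliquot
#'   (default 0.05, i.e. a 50 ul aliquot of 1 ml).
#' @return percent of input (vectorized).
#' @examples
#' chipPercentInput(25, 25)  # 5
#' chipPercentInput(25, 23)  # 20
#' @export
chipPercentInput <- function(ctInput, ctIp, inputFraction = 0.05) {
    .checkCt(ctInput, ctIp)
    if (any(inputFraction <= 0) || any(inputFraction > 1))
        stop("'inputFraction' must be in (0, 1]")
    2^(ctInput - ctIp) * inputFraction * 100
}

#' Input aliquot fraction from volumes
#'
#' @param aliquotVolume volume of the input aliquot.
#' @param totalVolume total chromatin volume (same units).
#' @return \code{aliquotVolume / totalVolume}.
#' @examples
#' inputFractionFromVolumes(50, 1000)  # 0.05
#' @export
inputFractionFromVolumes <- function(aliquotVolume, totalVolume) {
    if (any(aliquotVolume <= 0) || any(aliquotVolume > totalVolume))
        stop("need 0 < aliquotVolume <= totalVolume")
    aliquotVolume / totalVolume
}

#' Relative expression by the delta-CT method
#'
#' \code{2^(ctHousekeeping - ctGene)}: one cycle below the housekeeping
#' gene means two-fold higher expression.  When CTs for several
#' housekeeping genes are supplied (a list or a matrix with one row per
#' reference), the single-reference ratios are combined by their
#' geometric mean.
#'
#' @param ctGene CT values of the gene of interest.
#' @param ctHousekeeping CT values of the housekeeping gene; or a list /
#'   matrix (rows = references) for multi-reference normalization.
#' @return linear expression ratio (vectorized).
#' @examples
#' relativeExpression(25, 25)        # 1
#' relativeExpression(28, 25)        # 0.125
#' relativeExpression(24, list(25, 27))  # geometric mean of 2 and 8 = 4
#' @export
relativeExpression <- function(ctGene, ctHousekeeping) {
    if (is.list(ctHousekeeping))
        ctHousekeeping <- do.call(rbind, ctHousekeeping)
    if (is.matrix(ctHousekeeping))
        ctHousekeeping <- colMeans(ctHousekeeping)
    .checkCt(ctGene, ctHousekeeping)
    2^(ctHousekeeping - ctGene)
}

#' Average technical replicate CTs
#'
#' Replicate CT values are averaged on the CT (cycle) scale, before any
#' delta-CT arithmetic.
#'
#' @param ct numeric CT values.
#' @param by grouping labels (one per CT value).
#' @return named numeric vector of mean CTs per group.
#' @export
averageCt <- function(ct, by) {
    .checkCt(ct)
    res <- tapply(ct, by, mean)
    stats::setNames(as.numeric(res), names(res))[unique(as.character(by))]
}

#' Normalize to the highest value (set to 100)
#'
#' Scales expression ratios so the highest entry becomes exactly 100.
#' Scale-invariant: multiplying all inputs by a positive constant leaves
#' the output unchanged.
#'
#' @param values named numeric vector of expression ratios (>= 0, at
#'   least one positive).
#' @return named numeric vector with max = 100.
#' @examples
#' normalizeToMax(c(A = 2, B = 1))  # A = 100, B = 50
#' @export
normalizeToMax <- function(values) {
    if (length(values) == 0L || all(values == 0))
        stop("need at least one positive value")
    if (any(values < 0)) stop("negative expression ratio")
    values * 100 / max(values)
}

#' Normalize to a control (set to 1)
#'
#' Scales expression ratios so the control entry becomes exactly 1, the
#' convention for knockdown experiments.
#'
#' @param values named numeric vector of expression ratios.
#' @param controlLabel name of the control entry (must be present and
#'   positive).
#' @return named numeric vector with control = 1.
#' @examples
#' normalizeToControl(c(ctrl = 2, kd = 1), "ctrl")  # ctrl = 1, kd = 0.5
#' @export
normalizeToControl <- function(values, controlLabel) {
    if (!controlLabel %in% names(values))
        stop("control '", controlLabel, "' not found")
    ctrl <- values[[controlLabel]]
    if (!is.finite(ctrl) || ctrl <= 0)
        stop("control value must be positive")
    values / ctrl
}
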