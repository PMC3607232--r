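# Gene-set scoring in patient expression cohorts and clinical
# stratification: probe averaging, two-sided Wilcoxon comparisons with
# 2^(delta log2 mean) fold changes, MRD dichotomization at 0.01%, and
# Kaplan-Meier / log-rank survival analysis.

#' Per-sample expression of one gene
#'
#' The expression of a gene in a sample is the unweighted mean of the
#' log2 values of all probes mapped to that gene.
#'
#' @param cohort a \code{CohortExperiment}.
#' @param gene a gene symbol with at least one mapped probe.
#' @return named numeric vector, one value per sample (log2 scale).
#' @export
geneExpression <- function(cohort, gene) {
    stopifnot(is(cohort, "CohortExperiment"), length(gene) == 1L)
    sym <- rowData(cohort)$symbol
    rows <- which(!is.na(sym) & sym == gene)
    if (length(rows) == 0L)
        stop("gene '", gene, "' has no mapped probes")
    colMeans(assay(cohort, "log2")[rows, , drop = FALSE])
}

#' Per-sample gene-set score
#'
#' The score of a gene set in a sample is the mean over the set's mapped
#' genes of their per-gene expression (each gene itself the mean of its
#' probes).  Unmapped set members are counted and reported with a
#' message; an entirely unmapped set is an error.  The score is invariant
#' to the order of genes and probes.
#'
#' @param cohort a \code{CohortExperiment}.
#' @param geneset character vector of gene symbols.
#' @return named numeric vector, one score per sample (log2 scale).
#' @export
genesetScore <- function(cohort, geneset) {
    stopifnot(is(cohort, "CohortExperiment"))
    geneset <- unique(as.character(geneset))
    sym <- rowData(cohort)$symbol
    mapped <- geneset[geneset %in% sym]
    nUnmapped <- length(geneset) - length(mapped)
    if (length(mapped) == 0L)
        stop("none of the ", length(geneset),
             " gene-set members has a mapped probe")
    if (nUnmapped > 0L)
        message(nUnmapped, " gene-set member(s) without mapped probes ",
                "excluded from the score")
    perGene <- vapply(mapped, function(g) geneExpression(cohort, g),
                      numeric(ncol(cohort)))
    rowMeans(perGene)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Mann-Whitney U with midranks for ties; the p value is the exact
#' permutation probability when the pooled sample is tie-free and small
#' (\code{n_a + n_b <= exactLimit}), otherwise the normal approximation
#' with tie-corrected variance and continuity correction.  Two groups with
#' identical constant values are degenerate and return p = 1 with a
#' message.
#'
#' @param a,b numeric vectors (each non-empty).
#' @param exactLimit largest pooled sample size for which the exact
#'   tie-free p is computed (default 12).
#' @return list with elements \code{U} (U statistic of \code{a}) and
#'   \code{p} (two-sided).
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
wilcoxonRankSum <- function(a, b, exactLimit = 12) {
    a <- as.numeric(a); b <- as.numeric(b)
    if (length(a) < 1L || length(b) < 1L)
        stop("both groups must be non-empty")
    pooled <- c(a, b)
    if (length(unique(pooled)) == 1L) {
        message("all values identical across both groups; p = 1")
        return(list(U = length(a) * length(b) / 2, p = 1))
    }
    ties <- anyDuplicated(pooled) > 0L
    exact <- !ties && length(pooled) <= exactLimit
    wt <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = exact, correct = TRUE))
    list(U = unname(wt$statistic), p = min(1, wt$p.value))
}

#' Compare expression between two sample groups
#'
#' Scores every sample (a single gene via \code{\link{geneExpression}} or
#' a set via \code{\link{genesetScore}}), compares the two groups with a
#' two-sided Wilcoxon rank-sum test, and reports the linear fold change
#' \code{2^(mean_a - mean_b)} of the log2 group means.
#'
#' @param cohort a \code{CohortExperiment}.
#' @param labelA,labelB group labels of the stratifying variable.
#' @param gene single gene symbol (exclusive with \code{geneset}).
#' @param geneset character vector of symbols (exclusive with
#'   \code{gene}).
#' @param by name of the \code{colData} column holding the group labels
#'   (default \code{"subtype"}).
#' @return one-row \code{data.frame}: \code{group_a}, \code{group_b},
#'   \code{n_a}, \code{n_b}, \code{mean_a}, \code{mean_b} (log2),
#'   \code{u_statistic}, \code{p_two_sided}, \code{fold_change} (linear).
#' @export
compareGroups <- function(cohort, labelA, labelB, gene = NULL,
                          geneset = NULL, by = "subtype") {
    stopifnot(is(cohort, "CohortExperiment"))
    if (is.null(gene) == is.null(geneset))
        stop("supply exactly one of 'gene' or 'geneset'")
    if (!by %in% colnames(colData(cohort)))
        stop("no '", by, "' column in colData")
    grp <- as.character(colData(cohort)[[by]])
    for (lab in c(labelA, labelB))
        if (!lab %in% grp)
            stop("label '", lab, "' absent; available: ",
                 paste(sort(unique(grp[!is.na(grp)])), collapse = ", "))
    score <- if (!is.null(gene)) geneExpression(cohort, gene)
             else genesetScore(cohort, geneset)
    sa <- score[!is.na(grp) & grp == labelA]
    sb <- score[!is.na(grp) & grp == labelB]
    wt <- wilcoxonRankSum(sa, sb)
    data.frame(group_a = labelA, group_b = labelB,
               n_a = length(sa), n_b = length(sb),
               mean_a = mean(sa), mean_b = mean(sb),
               u_statistic = wt$U, p_two_sided = wt$p,
               fold_change = 2^(mean(sa) - mean(sb)))
}

#' Dichotomize minimal residual disease
#'
#' Samples with an MRD percentage at or above the threshold (default
#' 0.01\%) are MRD+, below it MRD-; samples without an MRD measurement
#' are "unknown" and excluded downstream.  The boundary value itself is
#' classified positive.
#'
#' @param x a \code{CohortExperiment} (with a \code{mrd_percent} colData
#'   column) or a numeric vector of MRD percentages (NA = missing).
#' @param threshold MRD threshold in percent (default 0.01).
#' @return factor with levels \code{MRD+}, \code{MRD-}, \code{unknown}.
#' @examples
#' mrdClassify(c(0.02, 0.005, NA, 0.01))
#' @export
mrdClassify <- function(x, threshold = 0.01) {
    mrd <- if (is(x, "CohortExperiment")) {
        if (!"mrd_percent" %in% colnames(colData(x)))
            stop("no 'mrd_percent' column in colData")
        colData(x)$mrd_percent
    } else as.numeric(x)
    if (any(mrd < 0, na.rm = TRUE))
        stop("negative MRD percentage")
    cls <- ifelse(is.na(mrd), "unknown",
                  ifelse(mrd >= threshold, "MRD+", "MRD-"))
    out <- factor(cls, levels = c("MRD+", "MRD-", "unknown"))
    if (is(x, "CohortExperiment")) names(out) <- colnames(x)
    out
}

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit survival curve; at tied times, deaths precede
#' censorings (the standard convention).  With no censoring the curve
#' equals the empirical survival function.
#'
#' @param times non-negative event/censoring times.
#' @param events 0/1 event indicators (1 = event, 0 = censored).
#' @return \code{data.frame} with columns \code{time}, \code{n_risk},
#'   \code{n_event}, \code{n_censor}, \code{survival}, one row per
#'   distinct observed time.
#' @examples
#' kmEstimate(c(1, 2, 3), c(1, 1, 1))$survival  # 2/3, 1/3, 0
#' @export
kmEstimate <- function(times, events) {
    if (length(times) == 0L) stop("empty survival input")
    if (length(times) != length(events))
        stop("'times' and 'events' lengths differ")
    if (any(times < 0)) stop("negative survival time")
    if (!all(events %in% c(0, 1))) stop("event indicators must be 0/1")
    fit <- survival::survfit(survival::Surv(times, events) ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, n_censor = fit$n.censor,
               survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank: at each event time the observed events per group
#' are compared with the hypergeometric expectation; the statistic is
#' chi-square with 1 df.  Exactly two groups, each non-empty.
#'
#' @param times,events as in \code{\link{kmEstimate}}.
#' @param groups group labels (exactly two distinct values).
#' @return list with \code{chiSquare} and \code{p}.
#' @export
logrankTest <- function(times, events, groups) {
    groups <- factor(groups)
    if (nlevels(groups) != 2L)
        stop("exactly two groups required, got ", nlevels(groups))
    if (any(tabulate(groups, 2L) < 1L))
        stop("each group needs at least one subject")
    if (length(times) != length(events) || length(times) != length(groups))
        stop("input lengths differ")
    sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
    chi <- unname(sd$chisq)
    list(chiSquare = chi, p = stats::pchisq(chi, df = 1,
                                            lower.tail = FALSE))
}

#' Expression comparison between MRD classes
#'
#' Classifies samples as MRD+/MRD- (unknowns excluded), optionally
#' restricts to a subset of subtypes, and runs
#' \code{\link{compareGroups}} with group A = MRD+ on a gene or gene set.
#'
#' @param cohort a \code{CohortExperiment}.
#' @param gene,geneset exactly one of the two, as in
#'   \code{\link{compareGroups}}.
#' @param subtypeFilter optional character vector of subtypes to keep
#'   (e.g. \code{"MLLr"}); \code{NULL} keeps all.
#' @param threshold MRD threshold in percent.
#' @return one-row \code{data.frame} as from \code{\link{compareGroups}}
#'   with \code{group_a = "MRD+"}.
#' @export
mrdExpressionReport <- function(cohort, gene = NULL, geneset = NULL,
                                subtypeFilter = NULL, threshold = 0.01) {
    stopifnot(is(cohort, "CohortExperiment"))
    keep <- rep(TRUE, ncol(cohort))
    if (!is.null(subtypeFilter))
        keep <- as.character(cohort$subtype) %in% subtypeFilter
    sub <- cohort[, keep]
    cls <- mrdClassify(sub, threshold)
    sub <- sub[, cls != "unknown"]
    cls <- cls[cls != "unknown"]
    if (sum(cls == "MRD+") < 1L || sum(cls == "MRD-") < 1L)
        stop("need at least one MRD+ and one MRD- sample after filtering")
    colData(sub)$mrd_class <- as.character(cls)
    compareGroups(sub, "MRD+", "MRD-", gene = gene, geneset = geneset,
                  by = "mrd_class")
}

#' Survival stratified by MRD class (or any annotation)
#'
#' Convenience wrapper: splits samples with complete survival data by MRD
#' class (or a given colData column), returns the per-group KM curves and
#' the two-group log-rank test.
#'
#' @param cohort a \code{CohortExperiment}.
#' @param endpoint \code{"os"} or \code{"rfs"} (expects
#'   \code{<endpoint>_time} / \code{<endpoint>_event} columns).
#' @param by \code{"mrd"} (dichotomized at \code{threshold}) or the name
#'   of a colData column with exactly two levels.
#' @param threshold MRD threshold in percent.
#' @return list with \code{curves} (named list of KM data.frames),
#'   \code{chiSquare}, \code{p}, \code{n} (subjects used).
#' @export
survivalByGroup <- function(cohort, endpoint = c("os", "rfs"), by = "mrd",
                            threshold = 0.01) {
    endpoint <- match.arg(endpoint)
    tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
    if (!all(c(tcol, ecol) %in% colnames(colData(cohort))))
        stop("cohort lacks ", tcol, "/", ecol, " columns")
    grp <- if (identical(by, "mrd")) as.character(mrdClassify(cohort,
                                                              threshold))
           else as.character(colData(cohort)[[by]])
    times <- colData(cohort)[[tcol]]; events <- colData(cohort)[[ecol]]
    ok <- !is.na(times) & !is.na(events) & !is.na(grp) & grp != "unknown"
    grp <- factor(grp[ok]); times <- times[ok]; events <- events[ok]
    lr <- logrankTest(times, events, grp)
    curves <- lapply(split(seq_along(times), grp), function(i)
        kmEstimate(times[i], events[i]))
    list(curves = curves, chiSquare = lr$chiSquare, p = lr$p,
         n = sum(ok))
}

#' Read cohort files
#'
#' \code{readExpressionTsv} reads a probes x samples TSV of log2 values
#' (first column probe ids, header sample ids); \code{readProbeMap} a
#' two-column TSV (probe_id, symbol); \code{readSampleAnnotations} a TSV
#' with header containing at least sample_id and subtype.
#' \code{readCohort} assembles the three into a \code{CohortExperiment}.
#'
#' @param path file path.
#' @return see Description.
#' @export
readExpressionTsv <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    storage.mode(m) <- "numeric"
    if (anyNA(m)) stop("missing expression values in ", path)
    m
}

#' @rdname readExpressionTsv
#' @export
readProbeMap <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    if (!all(c("probe_id", "symbol") %in% colnames(df)))
        stop("probe map needs columns probe_id, symbol")
    df
}

#' @rdname readExpressionTsv
#' @export
readSampleAnnotations <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
}

#' @param exprPath,mapPath,annPath paths to the three cohort files.
#' @rdname readExpressionTsv
#' @export
readCohort <- function(exprPath, mapPath, annPath) {
    cohortExperiment(readExpressionTsv(exprPath), readProbeMap(mapPath),
                     readSampleAnnotations(annPath))
}

#' Write cohort files
#'
#' Writes the three TSVs that \code{\link{readCohort}} reads back.
#'
#' @param cohort a \code{CohortExperiment}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisible character vector of the three paths.
#' @export
writeCohortTsv <- function(cohort, dir, prefix = "cohort") {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    pExpr <- file.path(dir, paste0(prefix, "_expression.tsv"))
    pMap <- file.path(dir, paste0(prefix, "_probe_map.tsv"))
    pAnn <- file.path(dir, paste0(prefix, "_annotations.tsv"))
    m <- assay(cohort, "log2")
    utils::write.table(data.frame(probe_id = rownames(m), m,
                                  check.names = FALSE),
                       pExpr, sep = "\t", quote = FALSE, row.names = FALSE)
    sym <- rowData(cohort)$symbol
    utils::write.table(data.frame(probe_id = rownames(m),
                                  symbol = sym)[!is.na(sym), ],
                       pMap, sep = "\t", quote = FALSE, row.names = FALSE)
    ann <- data.frame(sample_id = colnames(cohort),
                      as.data.frame(colData(cohort)),
                      check.names = FALSE, row.names = NULL)
    utils::write.table(ann, pAnn, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(pExpr, pMap, pAnn))
}
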