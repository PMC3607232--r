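# Independent brute-force oracles used across the suite.  These are
# deliberately naive (plain vectors, explicit loops) and share no code
# with the package implementation.

# -- naive fragment extension + per-base pileup ---------------------------
# reads: data.frame(chrom, start (1-based), length, strand)
naivePileup <- function(reads, fraglen, chromSizes) {
    cov <- lapply(chromSizes, function(n) integer(n))
    for (i in seq_len(nrow(reads))) {
        chr <- reads$chrom[i]
        if (reads$strand[i] == "+") {
            s <- reads$start[i]; e <- s + fraglen - 1L
        } else {
            e <- reads$start[i] + reads$length[i] - 1L
            s <- e - fraglen + 1L
        }
        s <- max(1L, s); e <- min(chromSizes[[chr]], e)
        if (s <= e) cov[[chr]][s:e] <- cov[[chr]][s:e] + 1L
    }
    cov
}

# -- naive per-base threshold + run merge peak caller ---------------------
# Returns data.frame(chrom, start, end, summit, height, fold).
naiveCallPeaks <- function(ipCov, ipTotal, inCov, inTotal, fraglen,
                           genomeSize, t, f, mergeGap, minWidth) {
    lambda <- ipTotal * fraglen / genomeSize
    out <- list()
    for (chr in names(ipCov)) {
        cov <- ipCov[[chr]]
        hot <- cov >= t * lambda
        fold <- rep(NA_real_, length(cov))
        if (!is.null(inCov)) {
            lambdaIn <- inTotal * fraglen / genomeSize
            flo <- pmax(inCov[[chr]], lambdaIn)
            fold <- (cov / ipTotal) / (flo / inTotal)
            hot <- hot & fold >= f
        }
        # explicit scan: collect hot runs, then merge gaps <= mergeGap
        runs <- list(); i <- 1L; n <- length(hot)
        while (i <= n) {
            if (hot[i]) {
                j <- i
                while (j < n && hot[j + 1L]) j <- j + 1L
                runs[[length(runs) + 1L]] <- c(i, j)
                i <- j + 1L
            } else i <- i + 1L
        }
        merged <- list()
        for (r in runs) {
            k <- length(merged)
            if (k > 0L && r[1] - merged[[k]][2] - 1L <= mergeGap)
                merged[[k]][2] <- r[2]
            else merged[[k + 1L]] <- r
        }
        for (r in merged) {
            if (r[2] - r[1] + 1L < minWidth) next
            span <- r[1]:r[2]
            hotIdx <- span[hot[span]]
            summit <- hotIdx[which.max(cov[hotIdx])]
            out[[length(out) + 1L]] <- data.frame(
                chrom = chr, start = r[1], end = r[2], summit = summit,
                height = cov[summit] / lambda, fold = fold[summit])
        }
    }
    if (!length(out))
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), summit = integer(),
                          height = numeric(), fold = numeric()))
    do.call(rbind, out)
}

# package peaks GRanges -> comparable data.frame
peaksToDf <- function(peaks) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                     start = GenomicRanges::start(peaks),
                     end = GenomicRanges::end(peaks),
                     summit = peaks$summit, height = peaks$height,
                     fold = peaks$fold_vs_input)
    df[order(df$chrom, df$start), , drop = FALSE]
}

# -- exhaustive-permutation two-sided Wilcoxon ----------------------------
enumWilcoxonP <- function(a, b) {
    pooled <- c(a, b); na <- length(a); n <- length(pooled)
    r <- rank(pooled)
    uOf <- function(idx) sum(r[idx]) - na * (na + 1) / 2
    uObs <- uOf(seq_len(na))
    us <- apply(utils::combn(n, na), 2L, uOf)
    pLo <- mean(us <= uObs); pHi <- mean(us >= uObs)
    min(1, 2 * min(pLo, pHi))
}

# -- naive Venn partition counts ------------------------------------------
naivePartition <- function(sets) {
    sets <- lapply(sets, function(s) unique(toupper(trimws(s))))
    counts <- list()
    for (el in unique(unlist(sets))) {
        sig <- paste(names(sets)[vapply(sets, function(s) el %in% s,
                                        logical(1))], collapse = "&")
        counts[[sig]] <- (counts[[sig]] %||% 0L) + 1L
    }
    unlist(counts)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

# -- small builders --------------------------------------------------------
gene <- function(chrom, start1, end1, strand, id = "g1", sym = toupper(id)) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1),
                           strand = strand, gene_id = id, symbol = sym)
}

readsGR <- function(chrom, starts, strand = "+", len = 36L) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, width = len),
                           strand = strand)
}

# random toy read set on a small genome, as both a data.frame (for the
# oracle) and a GRanges (for the implementation)
randomToyReads <- function(n, chromSizes, len = 36L) {
    chrom <- sample(names(chromSizes), n, replace = TRUE)
    start <- vapply(chrom, function(ch)
        sample.int(chromSizes[[ch]] - len + 1L, 1L), integer(1))
    df <- data.frame(chrom = chrom, start = start, length = len,
                     strand = sample(c("+", "-"), n, replace = TRUE),
                     stringsAsFactors = FALSE)
    list(df = df,
         gr = GenomicRanges::GRanges(df$chrom,
                                     IRanges::IRanges(df$start, width = len),
                                     strand = df$strand))
}

# a tiny cohort fixture with known values
tinyCohort <- function() {
    m <- rbind(TP53_p1 = c(2, 4, 6), TP53_p2 = c(4, 6, 8),
               MYC_p1 = c(5, 5, 5), UNMAPPED_p = c(1, 1, 1))
    colnames(m) <- c("s1", "s2", "s3")
    pm <- data.frame(probe_id = c("TP53_p1", "TP53_p2", "MYC_p1"),
                     symbol = c("TP53", "TP53", "MYC"))
    ann <- data.frame(sample_id = c("s1", "s2", "s3"),
                      subtype = c("MLLr", "MLLr", "other"),
                      mrd_percent = c(0.02, NA, 0.005))
    cohortExperiment(m, pm, ann)
}
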