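# Clonal-read collapsing, fragment pileup, and the fold-over-background
# peak caller, checked against hand values and the naive per-base oracle.

test_that("clonal reads collapse to one per (chrom, start, strand)", {
    r <- suppressWarnings(c(readsGR("chr1", c(101, 101, 101), "+"),
                            readsGR("chr1", 101, "-"),
                            readsGR("chr2", 101, "+")))
    dd <- deduplicateReads(r)
    expect_equal(length(dd), 3L)
    # order independence
    expect_identical(deduplicateReads(rev(r)), dd)
    expect_equal(length(deduplicateReads(r[0])), 0L)
})

test_that("fragment extension follows the 5' end and conserves mass", {
    sizes <- c(chr1 = 1e5)
    # + read at 0-based 1000 -> fragment [1000,1170)
    tr <- fragmentCoverage(readsGR("chr1", 1001, "+"), 170, sizes)
    v <- as.integer(tr@coverage[["chr1"]])
    expect_equal(which(v == 1L), 1001:1170)
    # - read, 0-based start 1000, length 36 -> fragment [866,1036)
    tr2 <- fragmentCoverage(readsGR("chr1", 1001, "-", 36L), 170, sizes)
    expect_equal(which(as.integer(tr2@coverage[["chr1"]]) == 1L), 867:1036)
    # two identical fragments stack
    tr3 <- fragmentCoverage(readsGR("chr1", c(1001, 1001), "+"), 170, sizes)
    expect_equal(max(tr3@coverage[["chr1"]]), 2L)
    expect_equal(sum(sum(tr3@coverage)), 2 * 170)
    # truncation at the chromosome end is reported and mass shrinks
    expect_message(
        tr4 <- fragmentCoverage(readsGR("chr1", 99990, "+"), 170, sizes),
        "truncated")
    expect_equal(sum(sum(tr4@coverage)), 1e5 - 99990 + 1)
})

test_that("a single stack over empty background yields the hand peak", {
    # 40 fragments on 0-based [1000,1170) of a 100 kb genome, no input:
    # lambda = 40*170/1e5 = 0.068, height = 40/0.068
    sizes <- c(chr1 = 1e5)
    tr <- fragmentCoverage(readsGR("chr1", rep(1001, 40), "+"), 170, sizes)
    pk <- callPeaks(tr, config = peakCallerConfig(t = 15))
    expect_equal(length(pk), 1L)
    expect_equal(c(start(pk), end(pk)), c(1001, 1170))
    expect_true(pk$summit >= start(pk) && pk$summit <= end(pk))
    expect_equal(pk$height, 40 / 0.068, tolerance = 1e-12)
    expect_true(is.na(pk$fold_vs_input))
})

test_that("no enrichment anywhere gives an empty peak list", {
    set.seed(1)
    sizes <- c(chr1 = 5e4)
    tr <- fragmentCoverage(readsGR("chr1", sample(1:49000, 300)), 170, sizes)
    pk <- callPeaks(tr, config = peakCallerConfig(t = 15))
    expect_equal(length(pk), 0L)
})

test_that("mergeGap joins nearby stacks; small gaps keep them apart", {
    sizes <- c(chr1 = 1e5)
    # stacks at 0-based [1000,1170) and [1270,1440): 100 bp apart
    r <- readsGR("chr1", c(rep(1001, 30), rep(1271, 30)), "+")
    tr <- fragmentCoverage(r, 170, sizes)
    one <- callPeaks(tr, config = peakCallerConfig(t = 15, mergeGap = 170))
    two <- callPeaks(tr, config = peakCallerConfig(t = 15, mergeGap = 50))
    expect_equal(length(one), 1L)
    expect_equal(length(two), 2L)
    expect_equal(c(start(one), end(one)), c(1001, 1440))
})

test_that("input gate suppresses regions equally covered in input", {
    sizes <- c(chr1 = 1e5)
    ipR <- readsGR("chr1", rep(c(1001, 5001), each = 40), "+")
    inR <- readsGR("chr1", rep(5001, 40), "+")
    ip <- fragmentCoverage(ipR, 170, sizes)
    inp <- fragmentCoverage(inR, 170, sizes)
    pk <- callPeaks(ip, inp, peakCallerConfig(t = 15, f = 2))
    expect_equal(length(pk), 1L)
    expect_equal(start(pk), 1001)
    expect_true(pk$fold_vs_input >= 2)
})

test_that("degenerate inputs error informatively", {
    sizes <- c(chr1 = 1e4)
    empty <- fragmentCoverage(readsGR("chr1", 1)[0], 170, sizes)
    expect_error(callPeaks(empty), "zero fragments")
    ip <- fragmentCoverage(readsGR("chr1", rep(1001, 40)), 170, sizes)
    inp <- fragmentCoverage(readsGR("chr2", 1001), 170, c(chr2 = 1e4))
    expect_error(callPeaks(ip, inp, peakCallerConfig()), "differ")
    expect_error(fragmentCoverage(readsGR("chrX", 10), 170, sizes),
                 "chrX")
})

test_that("caller matches the naive oracle on random toy genomes", {
    set.seed(101)
    for (rep in 1:12) {
        sizes <- c(a = sample(8000:20000, 1), b = sample(5000:15000, 1))
        n <- sample(100:400, 1)
        toy <- randomToyReads(n, sizes)
        withInput <- rep %% 2 == 0
        inToy <- if (withInput) randomToyReads(n, sizes) else NULL
        # spike a couple of stacks so some peaks exist
        spike <- readsGR("a", rep(sample(2000:5000, 1), 25), "+")
        gr <- c(toy$gr, spike)
        df <- rbind(toy$df, data.frame(chrom = "a", start = start(spike),
                                       length = 36L, strand = "+"))
        cfg <- peakCallerConfig(t = sample(c(5, 10, 15), 1), f = 2,
                                fraglen = 170,
                                mergeGap = sample(c(0, 50, 170), 1))
        ipTr <- fragmentCoverage(gr, cfg@fraglen, sizes)
        inTr <- if (withInput)
            fragmentCoverage(inToy$gr, cfg@fraglen, sizes) else NULL
        got <- peaksToDf(callPeaks(ipTr, inTr, cfg))
        want <- naiveCallPeaks(
            naivePileup(df, cfg@fraglen, sizes), length(gr),
            if (withInput) naivePileup(inToy$df, cfg@fraglen, sizes),
            if (withInput) nrow(inToy$df), cfg@fraglen, sum(sizes),
            cfg@t, cfg@f, cfg@mergeGap, cfg@minWidth)
        want <- want[order(want$chrom, want$start), , drop = FALSE]
        rownames(got) <- rownames(want) <- NULL
        expect_equal(got, want, tolerance = 1e-10)
    }
})

test_that("raising t or f never adds or widens peaks", {
    set.seed(7)
    sizes <- c(chr1 = 3e4)
    gr <- c(randomToyReads(300, sizes)$gr,
            readsGR("chr1", rep(4001, 30), "+"),
            readsGR("chr1", rep(9001, 18), "+"))
    inGr <- randomToyReads(300, sizes)$gr
    ip <- fragmentCoverage(gr, 170, sizes)
    inp <- fragmentCoverage(inGr, 170, sizes)
    base <- callPeaks(ip, inp, peakCallerConfig(t = 5, f = 1))
    for (cfg in list(peakCallerConfig(t = 10, f = 1),
                     peakCallerConfig(t = 5, f = 3),
                     peakCallerConfig(t = 15, f = 3))) {
        shr <- callPeaks(ip, inp, cfg)
        expect_lte(length(shr), length(base))
        # every surviving peak lies within some base peak
        if (length(shr))
            expect_true(all(IRanges::overlapsAny(shr, base, type = "within")))
    }
})

test_that("peaks are sorted, disjoint, and summits attain heights", {
    set.seed(11)
    sizes <- c(chr1 = 2e4, chr2 = 2e4)
    gr <- suppressWarnings(c(randomToyReads(400, sizes)$gr,
            readsGR("chr1", rep(3001, 25)), readsGR("chr2", rep(7001, 25))))
    ip <- fragmentCoverage(gr, 170, sizes)
    pk <- callPeaks(ip, config = peakCallerConfig(t = 10))
    expect_gt(length(pk), 0L)
    expect_false(is.unsorted(start(pk)[as.character(seqnames(pk)) == "chr1"]))
    expect_equal(length(GenomicRanges::findOverlaps(pk, drop.self = TRUE)),
                 0L)
    lambda <- expectedBackground(ip)
    for (i in seq_along(pk)) {
        chr <- as.character(seqnames(pk))[i]
        expect_equal(as.numeric(ip@coverage[[chr]][pk$summit[i]]) / lambda,
                     pk$height[i])
        expect_gte(pk$height[i], 10)
    }
})

test_that("reads and peaks round-trip through BED", {
    r <- suppressWarnings(c(readsGR("chr1", c(101, 500), "+"),
                            readsGR("chr2", 300, "-")))
    path <- withr::local_tempfile(fileext = ".bed")
    writeBedReads(r, path)
    back <- readBedReads(path)
    expect_equal(start(back), start(r))
    expect_equal(as.character(strand(back)), as.character(strand(r)))
    sizes <- c(chr1 = 1e5)
    tr <- fragmentCoverage(readsGR("chr1", rep(1001, 40), "+"), 170, sizes)
    pk <- callPeaks(tr, config = peakCallerConfig(t = 15))
    p2 <- withr::local_tempfile(fileext = ".bed")
    writePeaksBed(pk, p2)
    pb <- readPeaksBed(p2)
    expect_equal(start(pb), start(pk))
    expect_equal(pb$summit, pk$summit)
    expect_equal(pb$height, pk$height, tolerance = 1e-3)
})
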