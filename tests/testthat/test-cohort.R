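# Probe averaging, gene-set scores, Wilcoxon comparisons, MRD
# dichotomization and survival machinery.

test_that("gene expression is the probe mean; unmapped genes error", {
    ch <- tinyCohort()
    expect_equal(unname(geneExpression(ch, "TP53")), c(3, 5, 7))
    expect_equal(unname(geneExpression(ch, "MYC")), c(5, 5, 5))
    expect_error(geneExpression(ch, "NOPE"), "NOPE")
})

test_that("gene-set score averages genes and reports unmapped members", {
    ch <- tinyCohort()
    expect_equal(unname(genesetScore(ch, c("TP53", "MYC"))),
                 c(4, 5, 6))
    expect_message(s <- genesetScore(ch, c("TP53", "MYC", "GHOST")),
                   "1 gene-set member")
    expect_equal(unname(s), c(4, 5, 6))
    expect_error(genesetScore(ch, c("GHOST1", "GHOST2")))
    # invariance to gene order and probe order
    perm <- tinyCohort()[c(2, 3, 1), ]
    expect_equal(genesetScore(perm, c("MYC", "TP53")),
                 genesetScore(ch, c("TP53", "MYC")))
})

test_that("cohort construction enforces completeness and unique mapping", {
    m <- matrix(c(1, NA), 2, 1,
                dimnames = list(c("p1", "p2"), "s1"))
    pm <- data.frame(probe_id = c("p1", "p2"), symbol = c("A", "B"))
    ann <- data.frame(sample_id = "s1", subtype = "x")
    expect_error(cohortExperiment(m, pm, ann), "finite|missing")
    m2 <- matrix(1:4, 2, 2,
                 dimnames = list(c("p1", "p2"), c("s1", "s2")))
    pm2 <- data.frame(probe_id = c("p1", "p1", "p2"),
                      symbol = c("A", "B", "C"))
    ann2 <- data.frame(sample_id = c("s1", "s2"), subtype = "x")
    expect_warning(ch <- cohortExperiment(m2, pm2, ann2), "multiple genes")
    expect_true(is.na(rowData(ch)$symbol[1]))
})

test_that("Wilcoxon matches exact enumeration on the worked examples", {
    r1 <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))
    expect_equal(r1$U, 0)
    expect_equal(r1$p, 0.1)
    expect_equal(r1$p, enumWilcoxonP(c(1, 2, 3), c(4, 5, 6)))
    r2 <- wilcoxonRankSum(c(1, 2, 3, 4), c(10, 11, 12, 13))
    expect_equal(r2$p, 2 / 70)
    expect_equal(r2$p, enumWilcoxonP(c(1, 2, 3, 4), c(10, 11, 12, 13)))
    # identical multisets are perfectly symmetric
    expect_equal(wilcoxonRankSum(c(1, 5, 9), c(1, 5, 9))$p, 1)
    expect_message(r3 <- wilcoxonRankSum(c(2, 2), c(2, 2)), "identical")
    expect_equal(r3$p, 1)
})

test_that("Wilcoxon equals exhaustive permutation for tie-free samples", {
    set.seed(21)
    for (na in 1:5) for (nb in 1:5) {
        for (rep in 1:3) {
            x <- sample(seq(0, 1, length.out = 200), na + nb)
            a <- x[seq_len(na)]; b <- x[-seq_len(na)]
            expect_equal(wilcoxonRankSum(a, b)$p, enumWilcoxonP(a, b),
                         tolerance = 1e-12)
        }
    }
})

test_that("group comparison reports 2^(mean diff) fold change", {
    ch <- tinyCohort()
    cmp <- compareGroups(ch, "MLLr", "other", gene = "TP53")
    expect_equal(cmp$n_a, 2)
    expect_equal(cmp$n_b, 1)
    expect_equal(cmp$mean_a, 4)
    expect_equal(cmp$fold_change, 2^(4 - 7))
    expect_error(compareGroups(ch, "MLLr", "BCR-ABL", gene = "TP53"),
                 "available")
    # fold_change(a,b) * fold_change(b,a) = 1
    rev <- compareGroups(ch, "other", "MLLr", gene = "TP53")
    expect_equal(cmp$fold_change * rev$fold_change, 1)
    expect_equal(cmp$p_two_sided, rev$p_two_sided)
})

test_that("planted log2 shift is recovered as a two-fold change", {
    cfg <- syntheticConfig(seed = 42, nGenes = 20, nTargets = 6)
    sim <- makeCohort(cfg)
    cmp <- compareGroups(sim$cohort, "MLLr", "other",
                         geneset = plantedSymbols(sim$truth))
    expect_gt(cmp$fold_change, 1.5)
    expect_lt(cmp$p_two_sided, 0.05)
})

test_that("MRD classification uses the 0.01% threshold, >= positive", {
    cls <- mrdClassify(c(0.02, 0.005, NA, 0.01, 0))
    expect_equal(as.character(cls),
                 c("MRD+", "MRD-", "unknown", "MRD+", "MRD-"))
    expect_error(mrdClassify(-0.1), "negative")
    ch <- tinyCohort()
    expect_equal(as.character(mrdClassify(ch)),
                 c("MRD+", "unknown", "MRD-"))
})

test_that("KM product-limit matches hand computation", {
    km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
    expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
    # censoring: {1 event, 2 censored, 3 event}
    km2 <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
    expect_equal(km2$survival[km2$time == 1], 2 / 3)
    expect_equal(km2$survival[km2$time == 3], 0)
    # single censored subject: curve stays at 1
    km3 <- kmEstimate(5, 0)
    expect_true(all(km3$survival == 1))
    expect_equal(sum(km3$n_event), 0)
    expect_error(kmEstimate(numeric(), numeric()), "empty")
    expect_error(kmEstimate(c(1, 2), c(1, 2)), "0/1")
})

test_that("KM with no censoring equals the empirical survival function", {
    set.seed(33)
    for (i in 1:10) {
        tt <- sample(1:50, 12, replace = TRUE)
        km <- kmEstimate(tt, rep(1, 12))
        emp <- vapply(km$time, function(u) mean(tt > u), numeric(1))
        expect_equal(km$survival, emp)
    }
})

test_that("log-rank closed forms and symmetry", {
    # two subjects, event in A at t=1: O-E = 0.5, V = 0.25, chisq = 1
    lr <- logrankTest(c(1, 2), c(1, 0), c("A", "B"))
    expect_equal(lr$chiSquare, 1)
    # identical event patterns -> chisq 0, p 1
    lr0 <- logrankTest(c(1, 2, 1, 2), c(1, 1, 1, 1),
                       c("A", "A", "B", "B"))
    expect_equal(lr0$chiSquare, 0, tolerance = 1e-12)
    expect_equal(lr0$p, 1, tolerance = 1e-12)
    # label swap invariance
    set.seed(14)
    tt <- rexp(30); ev <- rbinom(30, 1, 0.8)
    gg <- rep(c("x", "y"), 15)
    a <- logrankTest(tt, ev, gg)
    b <- logrankTest(tt, ev, ifelse(gg == "x", "y", "x"))
    expect_equal(a$chiSquare, b$chiSquare)
    expect_error(logrankTest(1, 1, "A"), "two groups")
})

test_that("MRD expression report compares MRD+ vs MRD- with filters", {
    cfg <- syntheticConfig(seed = 8, nGenes = 20, nTargets = 6)
    sim <- makeCohort(cfg)
    rep1 <- mrdExpressionReport(sim$cohort,
                                geneset = plantedSymbols(sim$truth))
    expect_equal(rep1$group_a, "MRD+")
    expect_gt(rep1$fold_change, 1)   # planted 0.5 log2 coupling
    repM <- mrdExpressionReport(sim$cohort, subtypeFilter = "MLLr",
                                geneset = plantedSymbols(sim$truth))
    expect_lte(repM$n_a + repM$n_b, 20)
    expect_error(mrdExpressionReport(sim$cohort, gene = "GENE001",
                                     subtypeFilter = "absent-subtype"))
})

test_that("survival stratification by MRD runs the log-rank machinery", {
    cfg <- syntheticConfig(seed = 15, nGenes = 20, nTargets = 6)
    sim <- makeCohort(cfg)
    sv <- survivalByGroup(sim$cohort, "os", by = "mrd")
    expect_named(sv$curves, c("MRD+", "MRD-"), ignore.order = TRUE)
    expect_true(all(diff(sv$curves[["MRD+"]]$survival) <= 1e-12))
    expect_true(sv$p <= 1 && sv$p > 0)
    # planted hazard ratio 3 depresses the MRD+ curve (fixed seed)
    medSurv <- function(km) km$time[which(km$survival <= 0.5)[1]]
    expect_lt(medSurv(sv$curves[["MRD+"]]), medSurv(sv$curves[["MRD-"]]))
})

test_that("cohort files round-trip", {
    cfg <- syntheticConfig(seed = 4, nGenes = 10, nTargets = 3,
                           cohort = list(nHigh = 5, nOther = 8))
    sim <- makeCohort(cfg)
    dir <- withr::local_tempdir()
    paths <- writeCohortTsv(sim$cohort, dir)
    back <- readCohort(paths[1], paths[2], paths[3])
    expect_equal(assay(back, "log2"), assay(sim$cohort, "log2"))
    expect_equal(rowData(back)$symbol, rowData(sim$cohort)$symbol)
    expect_equal(back$subtype, sim$cohort$subtype)
    expect_equal(back$os_time, sim$cohort$os_time)
})
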