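test_that("adaptor clipping removes end matches and drops short survivors", {
    ad <- "TGGAATTCTCGG"
    # no adaptor anywhere: unchanged
    expect_identical(clipAdaptor("ACGTACGTACGTACGTACGTAC", ad),
                     "ACGTACGTACGTACGTACGTAC")
    # last 10 nt equal the adaptor prefix: 10-nt remainder -> dropped
    rd <- paste0("ACGTACGTAC", substr(ad, 1, 10))
    expect_identical(clipAdaptor(rd, ad), NA_character_)
    # internal full adaptor: clipped from its start to the read end
    rd2 <- paste0(strrep("ACGT", 5), ad, "AAAA")
    expect_identical(clipAdaptor(rd2, ad), strrep("ACGT", 5))
    # 5' end partial match (adaptor suffix at read start)
    rd3 <- paste0(substr(ad, 8, 12), strrep("ACGT", 5))
    expect_identical(clipAdaptor(rd3, ad), strrep("ACGT", 5))
    expect_error(clipAdaptor("ACGT", ""), "adaptor")
})

test_that("clipping agrees with an exhaustive substring oracle", {
    ad <- "TGGAATTCTCGGGTGCCAAGG"
    set.seed(42)
    reads <- vapply(1:200, function(i) {
        core <- paste(sample(c("A", "C", "G", "T"), sample(10:30, 1),
                             replace = TRUE), collapse = "")
        if (runif(1) < 0.5)
            paste0(core, substr(ad, 1, sample(1:nchar(ad), 1)))
        else core
    }, character(1))
    # oracle: longest clip over both ends, scanning every clip length
    oracle <- vapply(reads, function(rd) {
        L <- nchar(rd)
        c3 <- 0L
        for (len in L:1) {
            m <- min(len, nchar(ad))
            if (substr(rd, L - len + 1, L - len + m) == substr(ad, 1, m)) {
                c3 <- len; break
            }
        }
        c5 <- 0L
        for (len in min(L, nchar(ad)):1) {
            if (substr(rd, 1, len) ==
                substr(ad, nchar(ad) - len + 1, nchar(ad))) {
                c5 <- len; break
            }
        }
        out <- if (c3 >= c5 && c3 > 0) substr(rd, 1, L - c3)
               else if (c5 > 0) substr(rd, c5 + 1, L) else rd
        if (nchar(out) < 16) NA_character_ else out
    }, character(1), USE.NAMES = FALSE)
    expect_identical(clipAdaptor(reads, ad), oracle)
})

test_that("on-target counting follows the one-base-overlap rule", {
    # 0-based half-open read [100,120) and target [119,140): 1 base shared
    aln <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 120))
    tgt <- GenomicRanges::GRanges("chr1", IRanges::IRanges(120, 140))
    names(tgt) <- "miR-x"
    expect_identical(unname(countOnTarget(aln, tgt)), 1L)
    # read [100,119): zero overlap, not counted
    aln0 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 119))
    expect_identical(unname(countOnTarget(aln0, tgt)), 0L)
    # multi-target reads increment every overlapped target
    tgt2 <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(c(110, 115), c(130, 125)))
    names(tgt2) <- c("miR-a", "miR-b")
    expect_identical(unname(countOnTarget(aln, tgt2)), c(1L, 1L))
})

test_that("counting matches the brute-force oracle and is order-independent", {
    fx <- generateAlignments(nReads = 60, nTargets = 5, seed = 3)
    got <- countOnTarget(fx$alignments, fx$targets)
    expect_identical(got, bruteOverlapCounts(fx$alignments, fx$targets))
    shuffled <- fx$alignments[sample(length(fx$alignments))]
    expect_identical(countOnTarget(shuffled, fx$targets), got)
})

test_that("alignment and target region IO round-trips through SAM and BED", {
    fx <- generateAlignments(nReads = 25, nTargets = 3, seed = 9)
    sam <- tempfile(fileext = ".sam"); bed <- tempfile(fileext = ".bed")
    writeSamFile(fx$alignments, sam)
    writeTargetBed(fx$targets, bed)
    aln <- readSamAlignments(sam)
    tgt <- readTargetBed(bed)
    expect_identical(countOnTarget(aln, tgt)[names(fx$expected)],
                     fx$expected)
})

test_that("log2 ratios, centering and the t-test follow their definitions", {
    m <- matrix(c(3, 1, 1, 1,
                  7, 7, 7, 7), nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
    cc <- makeCounts(m, patient = c("P1", "P1", "P2", "P2"),
                     tissue = c("T", "N", "T", "N"))
    rat <- log2RatioTable(cc, "T/N", pseudocount = 1)
    expect_equal(rat["a", "P1"], 1)          # log2(4/2)
    expect_equal(rat["b", ], c(P1 = 0, P2 = 0))
    expect_error(log2RatioTable(makeCounts(matrix(0, 1, 2), c("P1", "P1"),
                                           c("T", "N")),
                                "T/N", pseudocount = 0), "pseudocount")

    expect_equal(medianCenter(c(1, 2, 3)), c(-1, 0, 1))
    expect_equal(medianCenter(medianCenter(c(4, -2, 7))),
                 medianCenter(c(4, -2, 7)))
    for (s in 1:20) {
        set.seed(s)
        x <- rnorm(sample(5:50, 1))
        expect_lt(abs(median(medianCenter(x))), 1e-12)
    }

    # hand-computed one-sample t
    x <- c(1, 1.1, 0.9, 1.2)
    res <- differentialTest(matrix(x, 1, dimnames = list("m", NULL)))
    tHand <- mean(x) / (sd(x) / sqrt(length(x)))
    expect_equal(res$t, tHand)
    expect_equal(res$p, 2 * pt(-abs(tHand), df = 3))
    # degenerate rows: p = 1, flagged
    z <- differentialTest(matrix(0, 1, 4))
    expect_equal(z$p, 1); expect_true(z$flag)
})

test_that("detection partition tiles the detected set", {
    m <- matrix(0L, 4, 6,
                dimnames = list(c("onlyT", "never", "all", "NM"), NULL))
    tissue <- c("N", "T", "M", "N", "T", "M")
    m["onlyT", 2] <- 5L
    m["all", ] <- 1L
    m["NM", c(1, 3)] <- 2L
    cc <- makeCounts(m, patient = rep(c("P1", "P2"), each = 3), tissue)
    pp <- detectionPartition(cc)
    expect_identical(pp$T, "onlyT")
    expect_identical(pp$NTM, "all")
    expect_identical(pp$NM, "NM")
    expect_false("never" %in% unlist(pp))
    # regions are disjoint and tile the detected set
    expect_identical(anyDuplicated(unlist(pp)), 0L)
    expect_setequal(unlist(pp), c("onlyT", "all", "NM"))

    # brute-force set algebra on a random cohort
    co <- generateCountCohort(CohortSpec(nMirnas = 80, nPlantedUp = 0,
                                         nPlantedDown = 0, meanLog = log(2),
                                         seed = 13))
    cts <- SummarizedExperiment::assay(co$counts)
    tis <- SummarizedExperiment::colData(co$counts)$tissue
    det <- lapply(c(N = "N", T = "T", M = "M"), function(tt)
        rownames(cts)[rowSums(cts[, tis == tt, drop = FALSE] > 0) > 0])
    pp2 <- detectionPartition(co$counts)
    expect_setequal(pp2$NTM, Reduce(intersect, det))
    expect_setequal(pp2$T, setdiff(det$T, union(det$N, det$M)))
    expect_setequal(unlist(pp2), unique(unlist(det)))
})

test_that("top lists rank by centered ratio under the p filter", {
    res <- data.frame(mirna = c("u1", "u2", "d1", "ns"),
                      meanRatio = c(3, 2, -3, 4),
                      t = 1, p = c(0.01, 0.02, 0.01, 0.5), n = 8,
                      flag = FALSE)
    tk <- topRegulated(res, k = 25, pMax = 0.05)
    expect_identical(tk$up$mirna, c("u1", "u2"))   # ns filtered by p
    expect_identical(tk$down$mirna, "d1")
    expect_identical(nrow(topRegulated(res, k = 0)$up), 0L)
    tkAll <- topRegulated(res, k = 100)
    expect_identical(nrow(tkAll$up), 2L)           # k beyond survivors
})

test_that("delta-delta-Ct arithmetic matches the definition", {
    ct <- data.frame(
        sample = rep(c("s1", "s2"), each = 2),
        tissue = rep(c("N", "T"), each = 2),
        gene = rep(c("RNU44", "miR-1"), 2),
        ct = c(25, 30, 25, 32))
    out <- deltaDeltaCt(ct)
    expect_equal(out$result$deltaDeltaCt, 2)   # dCt 7 vs 5
    expect_equal(out$result$foldChange, 0.25)
    # identical dCt in both tissues: ddCt 0, FC 1
    ct$ct <- c(25, 30, 25, 30)
    out2 <- deltaDeltaCt(ct)
    expect_equal(out2$result$deltaDeltaCt, 0)
    expect_equal(out2$result$foldChange, 1)
})
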