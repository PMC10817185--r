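test_that("normalisation divides by the autosomal median", {
    tr <- makeTrack(c(10, 10, 10, 5), c(a1 = 300000, cX = 100000), 100000)
    n <- normalizeCoverage(tr, "a1")
    expect_equal(normalizedCoverage(n), c(1, 1, 1, 0.5))
    expect_equal(autosomalMedian(n), 10)

    tr2 <- makeTrack(c(10, 10, 1000, 5), c(a1 = 300000, cX = 100000), 100000)
    expect_equal(autosomalMedian(normalizeCoverage(tr2, "a1")), 10)

    tr0 <- makeTrack(c(0, 0, 0, 5), c(a1 = 300000, cX = 100000), 100000)
    expect_error(normalizeCoverage(tr0, "a1"), "degenerate")
})

test_that("re-normalising an already-normalised track is the identity", {
    tr <- makeTrack(c(2, 1, 1, 0.5), c(a1 = 300000, cX = 100000), 100000)
    n1 <- normalizeCoverage(tr, "a1")
    again <- coverageTrack(windows(n1), normalizedCoverage(n1), "s", "male")
    n2 <- normalizeCoverage(again, "a1")
    expect_equal(normalizedCoverage(n2), normalizedCoverage(n1))
    expect_equal(autosomalMedian(n2), 1)
})

sixChromTrack <- function(xMedianFactor, sex, noise = 0.02, seed = 5) {
    set.seed(seed)
    lens <- setNames(rep(2e6, 6), c(paste0("c", 1:5), "c6"))
    w <- makeWindows(lens, 100000)
    f <- ifelse(as.character(seqnames(w)) == "c6", xMedianFactor, 1)
    coverageTrack(w, 30 * f * (1 + stats::rnorm(length(w), 0, noise)),
                  paste0("s_", sex), sex)
}

test_that("the X is the chromosome haploid in all males", {
    res <- inferX(list(sixChromTrack(0.5, "male"),
                       sixChromTrack(0.8, "female")))
    expect_equal(res$xChroms, "c6")
    maleCalls <- subset(res$ploidy, sex == "male")
    expect_equal(maleCalls$call[maleCalls$chrom == "c6"], "haploid")
    expect_true(all(maleCalls$call[maleCalls$chrom != "c6"] == "diploid"))
    ## female X dilution still classifies diploid at 0.8
    femCalls <- subset(res$ploidy, sex == "female")
    expect_equal(femCalls$call[femCalls$chrom == "c6"], "diploid")
    expect_lt(femCalls$medianN[femCalls$chrom == "c6"], 0.9)
})

test_that("multi-X karyotypes and X-less data are handled", {
    twoX <- function(sex, f6, f5) {
        set.seed(7)
        lens <- setNames(rep(2e6, 6), paste0("c", 1:6))
        w <- makeWindows(lens, 100000)
        ch <- as.character(seqnames(w))
        f <- ifelse(ch == "c6", f6, ifelse(ch == "c5", f5, 1))
        coverageTrack(w, 30 * f * (1 + stats::rnorm(length(w), 0, 0.02)),
                      sex, sex)
    }
    res <- inferX(list(twoX("male", 0.5, 0.5), twoX("female", 1, 1)))
    expect_setequal(res$xChroms, c("c5", "c6"))
    expect_warning(res0 <- inferX(list(twoX("male", 1, 1))), "not identified")
    expect_equal(res0$xChroms, character(0))
})

prm <- sharedRegionParams()

mkNormTrack <- function(N, sex) {
    w <- makeWindows(c(a1 = 1e6, chrX = length(N) * 1e5), 1e5)
    nAll <- c(rep(1, 10), N)
    methods::new("NormalizedCoverageTrack", windows = w, depth = nAll * 30,
                 sampleId = paste0("s", sex), sex = sex, N = nAll,
                 autosomalMedianDepth = 30, autosomes = "a1")
}

regionsFor <- function(classes, params = prm) {
    ## build male/female N producing exactly this classification
    nm <- ifelse(classes == "q", 1, ifelse(classes == "f", 0.5, 0.1))
    nf <- ifelse(classes == "m", 0.1, 1)
    callSharedRegions(mkNormTrack(nm, "male"), mkNormTrack(nf, "female"),
                      "chrX", params)
}

test_that("shared-region caller reproduces worked examples", {
    r1 <- regionsFor(rep("q", 12))
    expect_equal(width(r1), 1200000)
    expect_equal(r1$nBins, 12L)

    expect_equal(length(regionsFor(rep("q", 9))), 0L)

    r3 <- regionsFor(c(rep("q", 6), "f", "f", rep("q", 6)))
    expect_equal(width(r3), 1400000)
    expect_equal(r3$nGapBins, 2L)

    expect_equal(length(regionsFor(c(rep("q", 6), "f", "f", "f",
                                     rep("q", 6)))), 0L)
    expect_equal(length(regionsFor(rep("f", 12))), 0L)
})

test_that("bin classification handles zero and low female coverage", {
    classes <- karyoscope:::classifySharedBins(
        nMale = c(1.0, 1.0, 0.1, 0.3),
        nFemale = c(0.0, 1.0, 0.1, 1.0), params = prm)
    ## zero female with adequate male coverage is not female-dominated
    expect_equal(classes, c("q", "q", "m", "f"))
})

test_that("masked runs behave as gaps and long ones are reported", {
    cls <- c(rep("q", 11), "m", "m", rep("q", 11))
    r <- regionsFor(cls)
    expect_equal(width(r), 2400000)
    excl <- S4Vectors::metadata(r)$lowCoverageExclusions
    expect_equal(length(excl), 0L)

    cls2 <- c(rep("q", 11), rep("m", 14), rep("q", 11))
    r2 <- regionsFor(cls2)
    expect_equal(length(r2), 2L)
    excl2 <- S4Vectors::metadata(r2)$lowCoverageExclusions
    expect_equal(width(excl2), 1400000)
})

test_that("caller equals brute-force oracle on random vectors", {
    set.seed(31)
    for (i in 1:150) {
        n <- sample(1:14, 1)
        cls <- sample(c("q", "f", "m"), n, replace = TRUE)
        got <- callerSharedRegions(cls, 1e5, prm@mergeGap,
                                   prm@minRegionLength)
        want <- oracleSharedRegions(cls, 1e5, prm@mergeGap,
                                    prm@minRegionLength)
        expect_equal(got, want, info = paste(cls, collapse = ""))
    }
})

test_that("region count and extent are monotone in the thresholds", {
    set.seed(41)
    for (i in 1:40) {
        nm <- round(stats::runif(20, 0, 1.3), 2)
        nf <- round(stats::runif(20, 0.3, 1.3), 2)
        male <- mkNormTrack(nm, "male")
        female <- mkNormTrack(nf, "female")
        loose <- callSharedRegions(male, female, "chrX",
                                   sharedRegionParams(ratioThreshold = 0.6,
                                                      minRegionLength = 4e5))
        tight <- callSharedRegions(male, female, "chrX",
                                   sharedRegionParams(ratioThreshold = 0.9,
                                                      minRegionLength = 4e5))
        ## raising the ratio threshold never grows any region
        for (k in seq_along(tight))
            expect_true(any(start(loose) <= start(tight)[k] &
                            end(loose) >= end(tight)[k]))
        longer <- callSharedRegions(male, female, "chrX",
                                    sharedRegionParams(ratioThreshold = 0.6,
                                                       minRegionLength = 8e5))
        expect_lte(length(longer), length(loose))
    }
})

test_that("grid mismatches between the sexes are rejected", {
    male <- mkNormTrack(rep(1, 12), "male")
    w2 <- makeWindows(c(a1 = 1e6, chrX = 11e5), 1e5)
    female <- methods::new("NormalizedCoverageTrack", windows = w2,
                           depth = rep(30, length(w2)), sampleId = "f",
                           sex = "female", N = rep(1, length(w2)),
                           autosomalMedianDepth = 30, autosomes = "a1")
    expect_error(callSharedRegions(male, female, "chrX"), "grid")
})

test_that("region lengths in Mb match the published renderings", {
    expect_equal(regionLengthMb(22300000, 24943668), 2.6)
    expect_equal(regionLengthMb(22100000, 25485961), 3.4)
    expect_equal(regionLengthMb(13000000, 28232375), 15.2)
    expect_error(regionLengthMb(100, 100), "greater")
})
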