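test_that("fusion history shapes the chromosome count and composition", {
    lsig <- buildKaryotype(presetConfig("litomosoides", seed = 1))
    expect_equal(length(lsig@chromLengths), 6L)
    comp <- split(trueKaryotype(lsig)$nigon,
                  as.character(seqnames(trueKaryotype(lsig))))
    expect_setequal(unique(comp$chrX), c("X", "D"))
    autos <- setdiff(names(comp), "chrX")
    expect_true(all(vapply(comp[autos],
                           function(e) length(unique(e)) == 1, logical(1))))

    oncho <- buildKaryotype(presetConfig("onchocerca", seed = 1))
    expect_equal(length(oncho@chromLengths), 4L)
    expect_setequal(unique(split(trueKaryotype(oncho)$nigon,
        as.character(seqnames(trueKaryotype(oncho))))$chrX),
        c("X", "D", "E"))
})

test_that("an element cannot be fused twice", {
    cfg <- presetConfig("litomosoides", seed = 1)
    cfg@fusionHistory <- list(c("X", "D"), c("X", "D"))
    expect_error(buildKaryotype(cfg), "fused twice")
})

test_that("zero inversions leave element blocks contiguous", {
    cfg <- presetConfig("litomosoides", seed = 1)
    cfg@intermixInversions <- 0
    tr <- buildKaryotype(cfg)
    bx <- trueKaryotype(tr)[seqnames(trueKaryotype(tr)) == "chrX"]
    expect_equal(length(bx), 2L)
    expect_equal(rle(bx$nigon)$values, c("X", "D"))
})

test_that("a shared region outside the autosomal partition is rejected", {
    cfg <- presetConfig("brugia", seed = 1)
    cfg@sharedRegion <- c(1e6, 3e6)  # inside the ancient X+D partition
    expect_error(buildKaryotype(cfg), "autosomal partition")
})

test_that("marker capacity is enforced", {
    cfg <- presetConfig("litomosoides", seed = 1, scale = 1e-4)
    cfg@markersPerElement <- 1e5
    expect_error(placeMarkers(buildKaryotype(cfg)), "capacity")
})

test_that("male coverage is calibrated to N 0.5 off and 1.0 in the region", {
    offMed <- inMed <- numeric(20)
    for (s in 1:20) {
        tr <- buildKaryotype(presetConfig("brugia", seed = s))
        cm <- simulateCoverage(tr, "male")
        nm <- normalizeCoverage(cm, setdiff(names(tr@chromLengths), "chrX"))
        onX <- as.character(seqnames(windows(nm))) == "chrX"
        inReg <- IRanges::overlapsAny(windows(nm), tr@sharedRegion,
                                      type = "within")
        offMed[s] <- median(normalizedCoverage(nm)[onX & !inReg])
        inMed[s] <- median(normalizedCoverage(nm)[onX & inReg])
    }
    expect_true(all(abs(offMed - 0.5) <= 0.05))
    expect_true(all(abs(inMed - 1.0) <= 0.05))
})

test_that("planted SNP counts follow the configured rate", {
    tr <- buildKaryotype(presetConfig("dirofilaria", seed = 8))
    snps <- simulateSnps(tr)
    span <- width(tr@sharedRegion)
    lambda <- span / 2215
    ## Poisson count within 5 sigma of its mean
    expect_lt(abs(length(snps) - lambda), 5 * sqrt(lambda))
    ## all SNPs inside the planted region (no boundary bin configured)
    expect_true(all(IRanges::overlapsAny(snps, tr@sharedRegion)))

    ## rate zero -> empty table
    tr0 <- buildKaryotype(presetConfig("litomosoides", seed = 8))
    expect_equal(length(simulateSnps(tr0)), 0L)

    ## boundary elevation puts SNPs immediately left of the region
    trb <- buildKaryotype(presetConfig("brugia", seed = 8))
    sb <- simulateSnps(trb)
    leftBin <- GenomicRanges::GRanges("chrX",
        IRanges::IRanges(start(trb@sharedRegion) - 1e5,
                         start(trb@sharedRegion) - 1))
    nLeft <- sum(IRanges::overlapsAny(sb, leftBin))
    expect_gt(nLeft, 0)
    ## about 7x the in-region per-bp rate
    expect_lt(abs(nLeft - 7 * 1e5 / 2215), 5 * sqrt(7 * 1e5 / 2215))
})

test_that("emitted sequences carry telomere caps and paintable markers", {
    cfg <- presetConfig("litomosoides", seed = 2, scale = 0.01)
    tr <- buildKaryotype(cfg)
    gm <- emitGenomeAndMarkers(tr)
    for (nm in names(gm$genome)) {
        tc <- telomereCounts(as.character(gm$genome[[nm]]), chrom = nm)
        expect_equal(endsCapped(tc), c(left = TRUE, right = TRUE),
                     info = nm)
    }
    ## single-element chromosomes paint 100% one element
    painted <- assignNigon(gm$markers, gm$nigonMap)
    paint <- windowPaint(painted, makeWindows(tr@chromLengths, 5000))
    comp <- chromosomeComposition(paint)
    autos <- comp[comp$chrom != "chrX", ]
    fracCols <- paste0("frac_", NIGON_ELEMENTS)
    expect_true(all(apply(autos[, fracCols], 1, max) == 1))
})

test_that("fixture sets are byte-identical across reruns of one seed", {
    cfg <- presetConfig("brugia", seed = 5, scale = 0.005)
    d1 <- file.path(tempdir(), "fx1")
    d2 <- file.path(tempdir(), "fx2")
    m1 <- writeFixtureSet(cfg, d1)
    m2 <- writeFixtureSet(cfg, d2)
    expect_equal(m1$file, m2$file)
    expect_equal(m1$md5, m2$md5)
    ## a different seed changes the stochastic outputs
    m3 <- writeFixtureSet(presetConfig("brugia", seed = 6, scale = 0.005),
                          file.path(tempdir(), "fx3"))
    expect_false(all(m3$md5 == m1$md5))
})

test_that("fixture files round-trip through the pipeline readers", {
    cfg <- presetConfig("litomosoides", seed = 3, scale = 0.01)
    outdir <- file.path(tempdir(), "fx_lsig")
    writeFixtureSet(cfg, outdir)
    tr <- buildKaryotype(cfg)

    mk <- readBuscoMarkers(file.path(outdir, "busco_full_table.tsv"))
    map <- readNigonMap(file.path(outdir, "nigon_map.tsv"))
    expect_equal(length(mk), 7 * 300)
    painted <- assignNigon(mk, map)
    expect_false(any(painted$nigon == "unassigned"))

    covM <- readCoverageBed(file.path(outdir, "cov_male.bed"), "m", "male")
    covF <- readCoverageBed(file.path(outdir, "cov_female.bed"), "f",
                            "female")
    expect_equal(length(windows(covM)), length(windows(covF)))

    ## no neo-Y planted: the caller finds nothing on the X
    auto <- setdiff(names(tr@chromLengths), "chrX")
    reg <- callSharedRegions(normalizeCoverage(covM, auto),
                             normalizeCoverage(covF, auto), "chrX",
                             sharedRegionParams(binSize = cfg@binSize,
                                 mergeGap = 2 * cfg@binSize,
                                 minRegionLength = 1e6 * 0.01))
    expect_equal(length(reg), 0L)

    truth <- jsonlite::read_json(file.path(outdir, "truth.json"),
                                 simplifyVector = TRUE)
    expect_equal(truth$xChrom, "chrX")
    expect_setequal(truth$fusionComponents$chrX, c("X", "D"))
})
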