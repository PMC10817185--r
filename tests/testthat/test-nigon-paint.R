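mkMarkers <- function(df) {
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(df$start, df$start + 999),
                           markerId = df$id,
                           status = if (is.null(df$status))
                                        rep("complete", nrow(df))
                                    else df$status)
}

test_that("marker element assignment follows the map, preserving order", {
    mk <- mkMarkers(data.frame(chrom = "chr1",
                               start = c(100, 200, 300, 400),
                               id = c("idA", "idB", "idA", "idC")))
    map <- c(idA = "X", idC = "D")
    painted <- assignNigon(mk, map)
    expect_equal(painted$nigon, c("X", "unassigned", "X", "D"))
    expect_equal(painted$markerId, mk$markerId)
})

test_that("fragmented markers are excluded from painting by default", {
    mk <- mkMarkers(data.frame(chrom = "chr1", start = c(100, 200),
                               id = c("idA", "idB"),
                               status = c("complete", "fragmented")))
    painted <- assignNigon(mk, c(idA = "A", idB = "A"))
    expect_equal(painted$markerId, "idA")
    all3 <- assignNigon(mk, c(idA = "A", idB = "A"),
                        statuses = c("complete", "duplicated", "fragmented"))
    expect_equal(length(all3), 2L)
})

test_that("window painting counts markers by start with half-open bins", {
    ## 0-based starts 10,000 / 200,000 / 600,000 and one exactly at the
    ## 500 kb boundary (0-based 500,000 = 1-based 500,001)
    mk <- mkMarkers(data.frame(chrom = "chr1",
                               start = c(10001, 200001, 600001, 500001),
                               id = paste0("id", 1:4)))
    painted <- assignNigon(mk, setNames(rep("A", 4), paste0("id", 1:4)))
    w <- makeWindows(c(chr1 = 1000000), 500000)
    paint <- windowPaint(painted, w)
    expect_equal(paintCounts(paint)[, "A"], c(2L, 2L))
    ## conservation: window counts sum to assigned placed markers
    expect_equal(sum(paintCounts(paint)[, NIGON_ELEMENTS]), 4)
})

test_that("painting an empty marker set yields all-zero counts", {
    w <- makeWindows(c(chr1 = 1000000), 500000)
    painted <- assignNigon(mkMarkers(data.frame(chrom = character(),
                                                start = numeric(),
                                                id = character())),
                           c(idA = "A"))
    paint <- windowPaint(painted, w)
    expect_true(all(paintCounts(paint) == 0))
})

test_that("markers on unknown chromosomes are skipped with a warning", {
    mk <- mkMarkers(data.frame(chrom = c("chr1", "chrZZ"),
                               start = c(100, 100),
                               id = c("idA", "idB")))
    painted <- assignNigon(mk, c(idA = "A", idB = "B"))
    w <- makeWindows(c(chr1 = 1000000), 500000)
    expect_warning(paint <- windowPaint(painted, w), "skipped")
    expect_equal(paint@nSkipped, 1L)
    expect_equal(sum(paintCounts(paint)), 1)
})

test_that("fusion detection applies fraction and count thresholds", {
    buildPaint <- function(countsByElement, chromLen = 10e6) {
        starts <- c()
        ids <- c()
        els <- c()
        k <- 0
        for (el in names(countsByElement)) {
            n <- countsByElement[[el]]
            starts <- c(starts, seq(1, chromLen - 1000, length.out = n))
            ids <- c(ids, sprintf("%s%04d", el, seq_len(n) + k))
            els <- c(els, rep(el, n))
            k <- k + n
        }
        mk <- mkMarkers(data.frame(chrom = "chr1", start = round(starts),
                                   id = ids))
        painted <- assignNigon(mk, setNames(els, ids))
        windowPaint(painted, makeWindows(c(chr1 = chromLen), 500000))
    }
    f1 <- detectFusions(buildPaint(list(X = 120, D = 80)))
    expect_setequal(f1$chr1, c("X", "D"))
    f2 <- detectFusions(buildPaint(list(A = 200, B = 4)))
    expect_equal(f2$chr1, "A")
    f3 <- detectFusions(buildPaint(list(E = 60, X = 50, D = 40)))
    expect_setequal(f3$chr1, c("E", "X", "D"))
})

test_that("chromosomes without assigned markers are unpaintable", {
    mk <- mkMarkers(data.frame(chrom = "chr1", start = 100, id = "idA"))
    painted <- assignNigon(mk, c(somethingElse = "A"))
    w <- makeWindows(c(chr1 = 1000000), 500000)
    expect_error(detectFusions(windowPaint(painted, w)), "unpaintable")
})

test_that("runs statistic matches the closed form on tiny sequences", {
    r1 <- intermixingRuns(c("X", "X", "D", "D"))
    expect_equal(r1$runs, 2L)
    expect_equal(r1$expectedRuns, 3)
    expect_equal(r1$zScore, -sqrt(3 / 2), tolerance = 1e-12)
    expect_equal(round(r1$zScore, 4), -1.2247)

    r2 <- intermixingRuns(c("X", "D", "X", "D"))
    expect_equal(r2$runs, 4L)
    expect_equal(round(r2$zScore, 4), 1.2247)

    expect_error(intermixingRuns(c("X", "X", "X")), "runs undefined")
})

test_that("expected runs equals the enumeration mean for n1+n2 <= 8", {
    for (n1 in 1:4) for (n2 in n1:(8 - n1)) {
        if (n2 < 1) next
        labels <- c(rep("a", n1), rep("b", n2))
        expected <- intermixingRuns(labels)$expectedRuns
        expect_equal(expected, enumerateMeanRuns(n1, n2),
                     tolerance = 1e-12,
                     info = sprintf("n1=%d n2=%d", n1, n2))
    }
})

test_that("element sequences order by position with marker-id tiebreak", {
    mk <- mkMarkers(data.frame(chrom = "chr1",
                               start = c(300, 100, 100, 200),
                               id = c("d1", "b2", "a1", "c1")))
    painted <- assignNigon(mk, c(d1 = "D", b2 = "D", a1 = "X", c1 = "X"))
    expect_equal(elementSequence(painted, "chr1", c("X", "D")),
                 c("X", "D", "X", "D"))
})

test_that("synteny pairs keep markers single-copy in both genomes", {
    a <- assignNigon(mkMarkers(data.frame(
        chrom = "a1", start = c(100, 200, 300, 400),
        id = c("s1", "s2", "dup", "dup"),
        status = c("complete", "complete", "duplicated", "duplicated"))),
        c(s1 = "A", s2 = "B", dup = "C"))
    b <- assignNigon(mkMarkers(data.frame(
        chrom = "b1", start = c(900, 800),
        id = c("s1", "dup"))),
        c(s1 = "A", s2 = "B", dup = "C"))
    tab <- syntenyPairs(a, b)
    expect_equal(tab$markerId, "s1")
    expect_equal(tab$element, "A")
    expect_equal(tab$posB, 900)
    ## disjoint marker sets -> empty
    empty <- syntenyPairs(a[a$markerId == "s2"], b)
    expect_equal(nrow(empty), 0L)
})
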