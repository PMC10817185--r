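#' Normalise a coverage track by the autosomal median
#'
#' Divides each window's depth by the median depth over autosomal windows
#' (the median of all windows excluding those on the X), yielding the
#' normalised coverage N with expectation 1 for diploid and 0.5 for
#' haploid regions.
#'
#' @param track a [CoverageTrack-class].
#' @param autosomes character vector of chromosomes treated as autosomes.
#' @return A [NormalizedCoverageTrack-class].
#' @export
normalizeCoverage <- function(track, autosomes) {
    if (length(autosomes) == 0L)
        stop("autosome set must be non-empty", call. = FALSE)
    onAuto <- as.character(seqnames(windows(track))) %in% autosomes
    if (!any(onAuto))
        stop("no windows on the supplied autosomes", call. = FALSE)
    med <- stats::median(depth(track)[onAuto])
    if (!is.finite(med) || med <= 0)
        stop("degenerate coverage: autosomal median depth is zero",
             call. = FALSE)
    new("NormalizedCoverageTrack",
        windows = windows(track), depth = depth(track),
        sampleId = sampleId(track), sex = sampleSex(track),
        N = depth(track) / med,
        autosomalMedianDepth = med,
        autosomes = as.character(autosomes))
}

#' Classify per-chromosome ploidy from normalised coverage
#'
#' Calls each chromosome haploid, diploid or ambiguous from its median
#' normalised coverage. Thresholds default to midpoints around the
#' expected N of 0.5 (haploid) and 1.0 (diploid) with slack:
#' haploid for 0.3 <= median N < 0.75, diploid for 0.75 <= median N <= 1.3,
#' otherwise ambiguous.
#'
#' @param ntrack a [NormalizedCoverageTrack-class].
#' @param thresholds numeric(3): haploid lower bound, haploid/diploid
#'   boundary, diploid upper bound.
#' @return data.frame with columns `chrom`, `medianN`, `call`,
#'   `sampleId`, `sex`.
#' @export
classifyPloidy <- function(ntrack, thresholds = c(0.3, 0.75, 1.3)) {
    chroms <- as.character(seqnames(windows(ntrack)))
    med <- vapply(split(normalizedCoverage(ntrack), chroms),
                  stats::median, numeric(1))
    med <- med[unique(chroms)]  # keep grid order
    call <- ifelse(med >= thresholds[1] & med < thresholds[2], "haploid",
            ifelse(med >= thresholds[2] & med <= thresholds[3], "diploid",
                   "ambiguous"))
    data.frame(chrom = names(med), medianN = unname(med),
               call = unname(call), sampleId = sampleId(ntrack),
               sex = sampleSex(ntrack), stringsAsFactors = FALSE,
               row.names = NULL)
}

#' Identify the X chromosome(s) from sexed coverage tracks
#'
#' Two-pass procedure. The autosomal-median divisor excludes the X, but
#' the X is not known a priori: tracks are first normalised by the global
#' median over all windows and chromosomes haploid in all males are taken
#' as provisional X; tracks are then re-normalised with the
#' autosomal-only median and ploidy is re-called. Chromosomes haploid in
#' every male sample are reported as the X set (multi-X karyotypes are
#' supported). Female X coverage may legitimately sit below diploid
#' expectation when females carry embryos of both sexes.
#'
#' @param tracks list of raw [CoverageTrack-class] objects; at least one
#'   must have sex `"male"`.
#' @param thresholds passed to [classifyPloidy()].
#' @return list with `xChroms` (character, possibly empty, with a warning
#'   when empty), `ploidy` (row-bound ploidy calls from the final pass),
#'   and `tracks` (the re-normalised tracks).
#' @export
inferX <- function(tracks, thresholds = c(0.3, 0.75, 1.3)) {
    sexes <- vapply(tracks, sampleSex, character(1))
    if (!any(sexes == "male"))
        stop("at least one male track is required", call. = FALSE)
    allChroms <- unique(as.character(seqnames(windows(tracks[[1]]))))

    passX <- function(excluded) {
        autosomes <- setdiff(allChroms, excluded)
        norm <- lapply(tracks, normalizeCoverage, autosomes = autosomes)
        calls <- do.call(rbind, lapply(norm, classifyPloidy,
                                       thresholds = thresholds))
        maleCalls <- calls[calls$sex == "male", , drop = FALSE]
        hap <- vapply(split(maleCalls$call, maleCalls$chrom),
                      function(x) all(x == "haploid"), logical(1))
        list(x = names(hap)[hap], calls = calls, norm = norm)
    }

    pass1 <- passX(character())
    pass2 <- passX(pass1$x)
    if (length(pass2$x) == 0L)
        warning("no chromosome is haploid in all males; ",
                "X not identified (data may be mislabelled or non-X0/XY)",
                call. = FALSE)
    rownames(pass2$calls) <- NULL
    list(xChroms = pass2$x, ploidy = pass2$calls, tracks = pass2$norm)
}

## ---- shared-region caller ----

## classify X bins: "q" qualifying, "f" female-dominated, "m" masked
classifySharedBins <- function(nMale, nFemale, params) {
    masked <- nMale < params@lowCoverageN & nFemale < params@lowCoverageN
    ratioBelow <- ifelse(nFemale == 0, FALSE,
                         nMale / nFemale < params@ratioThreshold)
    ifelse(masked, "m", ifelse(ratioBelow, "f", "q"))
}

## Merge qualifying bins across small gaps and apply the length floor.
## classes: vector in {"q","f","m"}; starts/ends: 1-based closed bin
## coordinates on one chromosome (contiguous tiling). Gap span between
## consecutive qualifying bins is the summed length of the bins between
## them; a merged region is trimmed to its first/last qualifying bin.
mergeSharedBins <- function(classes, starts, ends, mergeGap,
                            minRegionLength) {
    qi <- which(classes == "q")
    empty <- data.frame(start = numeric(), end = numeric(),
                        nBins = integer(), nGapBins = integer())
    if (length(qi) == 0L) return(empty)
    newGroup <- c(TRUE, (starts[qi[-1]] - ends[qi[-length(qi)]] - 1) >
                        mergeGap)
    grp <- cumsum(newGroup)
    res <- lapply(split(qi, grp), function(ix) {
        data.frame(start = starts[ix[1]], end = ends[ix[length(ix)]],
                   nBins = length(ix),
                   nGapBins = as.integer(ix[length(ix)] - ix[1] + 1L -
                                         length(ix)))
    })
    out <- do.call(rbind, res)
    out <- out[out$end - out$start + 1 >= minRegionLength, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Call X-Y shared (male-diploid) regions on the X chromosome
#'
#' Implements the shared-region definition used for neo-Y detection:
#' large, semi-contiguous regions of the X where no bins are
#' female-dominated. Each X bin is classified as (1) masked when both
#' sexes have normalised coverage below `lowCoverageN` (inadequate data,
#' mechanising the manual exclusion of a low-coverage interval), (2)
#' female-dominated when the male-to-female N ratio is below
#' `ratioThreshold` (zero female coverage with adequate male coverage is
#' not female-dominated), (3) qualifying otherwise. Qualifying bins
#' separated by runs of non-qualifying bins spanning at most `mergeGap`
#' (inclusive) are merged; merged intervals, trimmed to their first and
#' last qualifying bins, are retained when at least `minRegionLength`
#' long. Masked runs longer than `mergeGap` are reported separately in
#' `metadata()$lowCoverageExclusions`.
#'
#' @param male,female [NormalizedCoverageTrack-class] objects on the
#'   identical window grid.
#' @param xChrom the X chromosome name.
#' @param params a [SharedRegionParams-class] object.
#' @return `GRanges` of shared regions with metadata columns `nBins` and
#'   `nGapBins`; `metadata()` carries `lowCoverageExclusions` (a
#'   `GRanges`) and `params`.
#' @export
callSharedRegions <- function(male, female, xChrom,
                              params = sharedRegionParams()) {
    wm <- windows(male); wf <- windows(female)
    if (!sameGrid(wm, wf))
        stop("male and female tracks are not on the same window grid",
             call. = FALSE)
    onX <- as.character(seqnames(wm)) == xChrom
    if (!any(onX))
        stop("chromosome '", xChrom, "' not present in the window grid",
             call. = FALSE)
    xw <- wm[onX]
    nm <- normalizedCoverage(male)[onX]
    nf <- normalizedCoverage(female)[onX]

    classes <- classifySharedBins(nm, nf, params)
    merged <- mergeSharedBins(classes, start(xw), end(xw),
                              params@mergeGap, params@minRegionLength)
    regions <- GRanges(rep(xChrom, nrow(merged)),
                       IRanges(start = merged$start, end = merged$end),
                       nBins = merged$nBins, nGapBins = merged$nGapBins)

    ## maximal masked runs longer than the merge gap: excluded, reported
    r <- rle(classes == "m")
    idxEnd <- cumsum(r$lengths)
    idxStart <- idxEnd - r$lengths + 1L
    maskedRuns <- which(r$values)
    excl <- GRanges()
    if (length(maskedRuns)) {
        s <- start(xw)[idxStart[maskedRuns]]
        e <- end(xw)[idxEnd[maskedRuns]]
        big <- (e - s + 1) > params@mergeGap
        excl <- GRanges(rep(xChrom, sum(big)),
                        IRanges(s[big], e[big]))
    }
    metadata(regions)$lowCoverageExclusions <- excl
    metadata(regions)$params <- params
    regions
}

#' Region length in megabases, to one decimal
#'
#' Converts a coordinate pair to a length in Mb rounded half-up to one
#' decimal, the convention used when reporting shared-region sizes.
#'
#' @param start,end region bounds in bp, `end > start`; the length is
#'   `end - start`.
#' @return numeric length in Mb with one decimal.
#' @examples
#' regionLengthMb(22300000, 24943668)  # 2.6
#' @export
regionLengthMb <- function(start, end) {
    if (any(end <= start))
        stop("end must be greater than start", call. = FALSE)
    roundHalfUp((end - start) / 1e6, 1)
}
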