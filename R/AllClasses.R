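#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   countOverlaps reduce pintersect tileGenome granges
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels Seqinfo
#' @importFrom BiocGenerics sort setdiff intersect
NULL

#' CoverageTrack: per-window read depth for one sexed sample
#'
#' Holds mean per-base read depth on a fixed window grid for a single
#' sample, together with the sample's sex. Depth values are reads-per-base
#' means (as produced by mosdepth-style windowed depth callers), so windows
#' of unequal length (the final window of a chromosome) remain comparable.
#'
#' @slot windows [GenomicRanges::GRanges] window grid (sorted,
#'   non-overlapping, tiling each chromosome).
#' @slot depth numeric, one mean depth per window, all >= 0.
#' @slot sampleId character(1) sample identifier.
#' @slot sex character(1), one of `"male"`, `"female"`, `"unknown"`.
#'
#' @seealso [coverageTrack()], [normalizeCoverage()]
#' @export
setClass("CoverageTrack",
    representation(
        windows = "GRanges",
        depth = "numeric",
        sampleId = "character",
        sex = "character"
    )
)

setValidity("CoverageTrack", function(object) {
    msg <- character()
    if (length(object@depth) != length(object@windows))
        msg <- c(msg, "one depth value per window is required")
    if (any(!is.finite(object@depth)) || any(object@depth < 0))
        msg <- c(msg, "depth values must be finite and >= 0")
    if (length(object@sex) != 1L ||
        !object@sex %in% c("male", "female", "unknown"))
        msg <- c(msg, "sex must be one of 'male', 'female', 'unknown'")
    if (length(object@sampleId) != 1L || is.na(object@sampleId))
        msg <- c(msg, "sampleId must be a single string")
    if (length(msg)) msg else TRUE
})

#' Construct a CoverageTrack
#'
#' @param windows `GRanges` window grid (see [makeWindows()]).
#' @param depth numeric vector of mean per-base depths, one per window.
#' @param sampleId single sample identifier.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @return A [CoverageTrack-class] object.
#' @examples
#' w <- makeWindows(c(chr1 = 300000), 100000)
#' coverageTrack(w, c(30, 31, 29), "s1", "male")
#' @export
coverageTrack <- function(windows, depth, sampleId, sex = "unknown") {
    new("CoverageTrack", windows = windows, depth = as.numeric(depth),
        sampleId = as.character(sampleId), sex = as.character(sex))
}

#' NormalizedCoverageTrack: depth divided by the autosomal median
#'
#' Extends [CoverageTrack-class] with the normalised coverage N, defined as
#' window depth divided by the median depth over autosomal windows. Under
#' this scaling a diploid region is expected at N = 1 and a haploid region
#' (the X in males of X0 species) at N = 0.5.
#'
#' @slot N numeric normalised coverage per window.
#' @slot autosomalMedianDepth numeric(1) divisor used.
#' @slot autosomes character, the chromosomes treated as autosomes.
#' @seealso [normalizeCoverage()], [classifyPloidy()]
#' @export
setClass("NormalizedCoverageTrack",
    contains = "CoverageTrack",
    representation(
        N = "numeric",
        autosomalMedianDepth = "numeric",
        autosomes = "character"
    )
)

setValidity("NormalizedCoverageTrack", function(object) {
    msg <- character()
    if (length(object@N) != length(object@windows))
        msg <- c(msg, "one N value per window is required")
    if (length(object@autosomalMedianDepth) != 1L ||
        !is.finite(object@autosomalMedianDepth) ||
        object@autosomalMedianDepth <= 0)
        msg <- c(msg, "autosomalMedianDepth must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' SharedRegionParams: parameters of the X-Y shared-region caller
#'
#' Bundles the thresholds used by [callSharedRegions()]. Defaults follow
#' the published procedure: a bin is female-dominated when the
#' male-to-female normalised coverage ratio is below 0.8; qualifying bins
#' separated by 200 kb or less are merged; merged regions at least 1 Mb
#' long are retained. `lowCoverageN` masks bins with inadequate coverage in
#' both sexes (N below the threshold), which behave as gaps during merging
#' and are reported separately.
#'
#' @slot ratioThreshold numeric(1), male/female N ratio below which a bin
#'   is female-dominated (default 0.8).
#' @slot binSize numeric(1) bin width in bp (default 100,000).
#' @slot mergeGap numeric(1) maximum bp span of a non-qualifying run that
#'   can be absorbed between qualifying bins (default 200,000).
#' @slot minRegionLength numeric(1) minimum region length in bp
#'   (default 1,000,000).
#' @slot lowCoverageN numeric(1) masking threshold on N (default 0.25).
#' @export
setClass("SharedRegionParams",
    representation(
        ratioThreshold = "numeric",
        binSize = "numeric",
        mergeGap = "numeric",
        minRegionLength = "numeric",
        lowCoverageN = "numeric"
    ),
    prototype(
        ratioThreshold = 0.8,
        binSize = 1e5,
        mergeGap = 2e5,
        minRegionLength = 1e6,
        lowCoverageN = 0.25
    )
)

setValidity("SharedRegionParams", function(object) {
    msg <- character()
    vals <- c(object@ratioThreshold, object@binSize, object@mergeGap,
              object@minRegionLength, object@lowCoverageN)
    if (length(vals) != 5L || any(!is.finite(vals)) || any(vals <= 0))
        msg <- c(msg, "all parameters must be single positive numbers")
    else if (object@mergeGap %% object@binSize != 0)
        msg <- c(msg, "mergeGap must be an integer multiple of binSize")
    if (length(msg)) msg else TRUE
})

#' @rdname SharedRegionParams-class
#' @param ratioThreshold,binSize,mergeGap,minRegionLength,lowCoverageN see
#'   the class slots.
#' @return A `SharedRegionParams` object.
#' @examples
#' sharedRegionParams()
#' sharedRegionParams(mergeGap = 3e5)
#' @export
sharedRegionParams <- function(ratioThreshold = 0.8, binSize = 1e5,
                               mergeGap = 2e5, minRegionLength = 1e6,
                               lowCoverageN = 0.25) {
    new("SharedRegionParams", ratioThreshold = ratioThreshold,
        binSize = binSize, mergeGap = mergeGap,
        minRegionLength = minRegionLength, lowCoverageN = lowCoverageN)
}

#' NigonPaint: windowed ancestral-element composition of chromosomes
#'
#' The result of painting ortholog markers onto a window grid: a count
#' matrix with one row per window and one column per Nigon element
#' (A, B, C, D, E, N, X) plus an `unassigned` column.
#'
#' @slot windows `GRanges` painting grid (nominal 500 kb windows).
#' @slot counts integer matrix, windows x elements.
#' @slot nSkipped integer(1), markers dropped because their chromosome is
#'   absent from the grid.
#' @seealso [windowPaint()], [detectFusions()], [chromosomeComposition()]
#' @export
setClass("NigonPaint",
    representation(
        windows = "GRanges",
        counts = "matrix",
        nSkipped = "integer"
    )
)

setValidity("NigonPaint", function(object) {
    msg <- character()
    if (nrow(object@counts) != length(object@windows))
        msg <- c(msg, "counts must have one row per window")
    need <- c(NIGON_ELEMENTS, "unassigned")
    if (!identical(colnames(object@counts), need))
        msg <- c(msg, paste("counts columns must be", paste(need, collapse = ", ")))
    if (any(object@counts < 0))
        msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
})

## ---- generics ----

#' @export
setGeneric("windows", function(x, ...) standardGeneric("windows"))
#' @export
setGeneric("depth", function(x, ...) standardGeneric("depth"))
#' @export
setGeneric("sampleId", function(x, ...) standardGeneric("sampleId"))
#' @export
setGeneric("sampleSex", function(x, ...) standardGeneric("sampleSex"))
#' @export
setGeneric("normalizedCoverage", function(x, ...)
    standardGeneric("normalizedCoverage"))
#' @export
setGeneric("autosomalMedian", function(x, ...)
    standardGeneric("autosomalMedian"))
#' @export
setGeneric("paintCounts", function(x, ...) standardGeneric("paintCounts"))

#' @describeIn CoverageTrack-class window grid accessor
#' @param x a `CoverageTrack`
#' @export
setMethod("windows", "CoverageTrack", function(x) x@windows)

#' @describeIn CoverageTrack-class depth accessor
#' @export
setMethod("depth", "CoverageTrack", function(x) x@depth)

#' @describeIn CoverageTrack-class sample identifier accessor
#' @export
setMethod("sampleId", "CoverageTrack", function(x) x@sampleId)

#' @describeIn CoverageTrack-class sample sex accessor
#' @export
setMethod("sampleSex", "CoverageTrack", function(x) x@sex)

#' @describeIn NormalizedCoverageTrack-class normalised coverage accessor
#' @param x a `NormalizedCoverageTrack`
#' @export
setMethod("normalizedCoverage", "NormalizedCoverageTrack", function(x) x@N)

#' @describeIn NormalizedCoverageTrack-class divisor accessor
#' @export
setMethod("autosomalMedian", "NormalizedCoverageTrack",
    function(x) x@autosomalMedianDepth)

#' @describeIn NigonPaint-class window grid accessor
#' @param x a `NigonPaint`
#' @export
setMethod("windows", "NigonPaint", function(x) x@windows)

#' @describeIn NigonPaint-class count matrix accessor
#' @export
setMethod("paintCounts", "NigonPaint", function(x) x@counts)

## ---- show methods ----

setMethod("show", "CoverageTrack", function(object) {
    cat("CoverageTrack for sample", object@sampleId,
        sprintf("(%s)\n", object@sex))
    cat(" ", length(object@windows), "windows on",
        length(seqlevels(object@windows)), "sequences\n")
    cat("  mean depth:", signif(mean(object@depth), 4), "\n")
})

setMethod("show", "NormalizedCoverageTrack", function(object) {
    callNextMethod()
    cat("  autosomal median depth:", signif(object@autosomalMedianDepth, 4),
        sprintf("(autosomes: %s)\n", paste(object@autosomes, collapse = ", ")))
})

setMethod("show", "SharedRegionParams", function(object) {
    cat("SharedRegionParams\n")
    cat("  ratioThreshold:", object@ratioThreshold,
        " binSize:", object@binSize, "\n")
    cat("  mergeGap:", object@mergeGap,
        " minRegionLength:", object@minRegionLength,
        " lowCoverageN:", object@lowCoverageN, "\n")
})

setMethod("show", "NigonPaint", function(object) {
    cat("NigonPaint:", nrow(object@counts), "windows,",
        sum(object@counts[, NIGON_ELEMENTS]), "assigned markers,",
        sum(object@counts[, "unassigned"]), "unassigned")
    if (object@nSkipped > 0L)
        cat(",", object@nSkipped, "skipped")
    cat("\n")
})
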