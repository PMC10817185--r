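## Internal numeric/formatting helpers shared across modules.

#' The seven ancestral Nigon elements
#'
#' Element alphabet of the rhabditid ancestral linkage groups:
#' five ancestrally autosomal elements (A-E), N, and the ancestrally
#' X-linked element X.
#' @export
NIGON_ELEMENTS <- c("A", "B", "C", "D", "E", "N", "X")

## round half away from zero (base round() is banker's rounding)
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

## thousands-separated integer rendering: 2215 -> "2,215"
formatBp <- function(x) {
    format(x, big.mark = ",", scientific = FALSE, trim = TRUE)
}

#' Render a region as a 1-based inclusive coordinate string
#'
#' Internal coordinates are held in `GRanges` (1-based, closed); reports
#' render regions in the `chrX:22,300,001-24,943,668` style used in
#' genome-assembly literature (1-based inclusive).
#'
#' @param region a `GRanges` of regions.
#' @return character vector of coordinate strings.
#' @examples
#' formatRegion(GenomicRanges::GRanges("chrX",
#'     IRanges::IRanges(22300001, 24943668)))
#' @export
formatRegion <- function(region) {
    sprintf("%s:%s-%s", as.character(seqnames(region)),
            formatBp(start(region)), formatBp(end(region)))
}

## identical window grids (seqnames + coordinates)
sameGrid <- function(a, b) {
    length(a) == length(b) &&
        identical(as.character(seqnames(a)), as.character(seqnames(b))) &&
        identical(start(a), start(b)) && identical(end(a), end(b))
}

## index of the window containing each 1-based position, given a uniform
## grid of `binSize` windows starting at 1 on one chromosome
stopifnotScalarPositive <- function(x, what) {
    if (length(x) != 1L || !is.finite(x) || x <= 0)
        stop(what, " must be a single positive number", call. = FALSE)
    invisible(x)
}
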