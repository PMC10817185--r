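#' Windowed heterozygous SNP density
#'
#' Counts heterozygous SNPs per window (nominal 50 kb, non-overlapping)
#' and divides by window length to give a per-bp density. A SNP is
#' counted in the window containing its position.
#'
#' @param snps `GRanges` of SNP positions from [readHetSnps()].
#' @param windows `GRanges` window grid from [makeWindows()].
#' @return `GRanges` of windows with metadata columns `count` and
#'   `density`; `metadata()$sampleId` is propagated from `snps`.
#' @export
snpDensity <- function(snps, windows) {
    sl <- seqlengths(windows)
    chrom <- as.character(seqnames(snps))
    bad <- !(chrom %in% names(sl)) | start(snps) > sl[chrom] |
        start(snps) < 1
    if (any(bad)) {
        i <- which(bad)[1]
        stop("SNP outside chromosome bounds: ", chrom[i], ":",
             start(snps)[i], call. = FALSE)
    }
    anchors <- GRanges(chrom, IRanges(start(snps), width = 1L))
    GenomeInfoDb::seqlevels(anchors) <- seqlevels(windows)
    out <- granges(windows)
    out$count <- countOverlaps(windows, anchors)
    out$density <- out$count / width(out)
    metadata(out)$sampleId <- metadata(snps)$sampleId
    out
}

#' Mean SNP density across samples
#'
#' Per-window arithmetic mean of several density tracks on the identical
#' grid (e.g. all male read sets of a species).
#'
#' @param tracks non-empty list of density `GRanges` from [snpDensity()].
#' @return `GRanges` with a `density` metadata column.
#' @export
meanDensity <- function(tracks) {
    if (length(tracks) == 0L)
        stop("at least one density track is required", call. = FALSE)
    ref <- tracks[[1]]
    for (t in tracks[-1])
        if (!sameGrid(ref, t))
            stop("density tracks are not on the same window grid",
                 call. = FALSE)
    out <- granges(ref)
    out$density <- rowMeans(vapply(tracks, function(t) t$density,
                                   numeric(length(ref))))
    out
}

#' Divergence summary for a region: SNP count, density and spacing
#'
#' Summarises heterozygous SNP load over a region (typically the
#' male-diploid X-Y shared region): total SNPs, span, mean density, and
#' the average spacing in bp per SNP, reported in the
#' "1 SNP every N bp" style with N rounded half-up to an integer.
#'
#' @param snps `GRanges` of SNP positions.
#' @param region `GRanges` of length 1.
#' @return data.frame with columns `region`, `nSnps`, `spanBp`,
#'   `density`, `spacingBp`, `spacingLabel` (NA when no SNPs fall in the
#'   region).
#' @examples
#' ## 1 SNP in 314 bp -> "1 SNP every 314 bp"
#' @export
regionSummary <- function(snps, region) {
    if (length(region) != 1L)
        stop("region must be a single interval", call. = FALSE)
    span <- width(region)
    if (span <= 0)
        stop("zero-length region", call. = FALSE)
    inside <- sum(as.character(seqnames(snps)) ==
                      as.character(seqnames(region)) &
                  start(snps) >= start(region) &
                  start(snps) <= end(region))
    if (inside > 0) {
        spacing <- roundHalfUp(span / inside, 0)
        label <- sprintf("1 SNP every %s bp", formatBp(spacing))
    } else {
        spacing <- NA_real_
        label <- NA_character_
    }
    data.frame(region = formatRegion(region), nSnps = inside,
               spanBp = span, density = inside / span,
               spacingBp = spacing, spacingLabel = label,
               stringsAsFactors = FALSE)
}

#' Windowed alignment coverage of Y contigs on the X
#'
#' Computes, per window, the fraction of bases covered by retained
#' alignments (the union of alignment target intervals, so overlapping
#' alignments are not double-counted).
#'
#' @param alignments filtered alignment table from [readAlignments()].
#' @param windows `GRanges` window grid (nominal 50 kb) whose
#'   `seqlengths` cover the alignment targets.
#' @return `GRanges` with a `fraction` metadata column in `[0, 1]`.
#' @seealso [weightedIdentity()]
#' @export
ycontigCoverage <- function(alignments, windows) {
    out <- granges(windows)
    if (nrow(alignments) == 0L) {
        out$fraction <- rep(0, length(windows))
        return(out)
    }
    gr <- alignmentRanges(alignments)
    sl <- seqlengths(windows)
    chrom <- as.character(seqnames(gr))
    bad <- !(chrom %in% names(sl)) | end(gr) > sl[chrom] | start(gr) < 1
    if (any(bad)) {
        i <- which(bad)[1]
        stop("alignment beyond target bounds: ", chrom[i], ":",
             start(gr)[i], "-", end(gr)[i], call. = FALSE)
    }
    GenomeInfoDb::seqlevels(gr) <- seqlevels(windows)
    covered <- reduce(granges(gr))
    hits <- findOverlaps(windows, covered)
    ov <- pintersect(windows[queryHits(hits)], covered[subjectHits(hits)])
    bp <- tapply(width(ov), factor(queryHits(hits),
                                   levels = seq_along(windows)), sum)
    bp[is.na(bp)] <- 0
    out$fraction <- as.numeric(bp) / width(windows)
    out
}

#' Length-weighted mean alignment identity
#'
#' Mean identity of retained alignments weighted by alignment length:
#' each alignment's identity is multiplied by its length and the sum is
#' divided by the total aligned length. Overlapping alignments each
#' contribute their full length (coverage and identity are two separate
#' summaries).
#'
#' @param alignments filtered alignment table from [readAlignments()].
#' @return numeric(1) percent identity, or `NA` when no alignments.
#' @examples
#' ## lengths 1000 and 3000 at 90 and 70 percent -> 75.0
#' @export
weightedIdentity <- function(alignments) {
    if (nrow(alignments) == 0L) return(NA_real_)
    sum(alignments$identity * alignments$length) / sum(alignments$length)
}
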