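#' Tile chromosomes into fixed-size, non-overlapping windows
#'
#' Builds the window grid used throughout the pipeline: windows of
#' `nominalSize` bp tile each chromosome end to end; the final window of a
#' chromosome may be shorter. Windows are returned as a `GRanges` carrying
#' the chromosome lengths in its `seqinfo`, with the nominal size recorded
#' in `metadata()`.
#'
#' @param chromLengths named numeric vector of chromosome lengths in bp.
#' @param nominalSize window size in bp (e.g. 100000 for coverage,
#'   500000 for painting, 50000 for SNP density, 200000 for repeats,
#'   1000 for telomere counting).
#' @return `GRanges` of windows, sorted within each chromosome.
#' @examples
#' makeWindows(c(c1 = 250001), 100000)  # 3 windows, last one short
#' @export
makeWindows <- function(chromLengths, nominalSize) {
    stopifnotScalarPositive(nominalSize, "nominalSize")
    if (length(chromLengths) == 0L || is.null(names(chromLengths)) ||
        any(!nzchar(names(chromLengths))))
        stop("chromLengths must be a named vector of chromosome lengths",
             call. = FALSE)
    if (any(!is.finite(chromLengths)) || any(chromLengths < 1))
        stop("all chromosome lengths must be >= 1", call. = FALSE)
    si <- Seqinfo(seqnames = names(chromLengths),
                  seqlengths = as.integer(chromLengths))
    ## tileGenome caps tilewidth at the genome size; windows wider than a
    ## chromosome still yield that chromosome's single short window
    tw <- min(as.integer(nominalSize), sum(as.integer(chromLengths)))
    gr <- tileGenome(si, tilewidth = tw, cut.last.tile.in.chrom = TRUE)
    metadata(gr)$nominalSize <- as.integer(nominalSize)
    gr
}

#' Read and write window/region sets as BED
#'
#' Thin wrappers over [rtracklayer::export()]/[rtracklayer::import()] so
#' that all on-disk interval files use the standard 0-based half-open BED
#' convention while in-memory objects are `GRanges`.
#'
#' @param x `GRanges` to write.
#' @param path file path.
#' @return `readBed()` returns a `GRanges`; `writeBed()` returns `path`
#'   invisibly.
#' @export
writeBed <- function(x, path) {
    rtracklayer::export(x, path, format = "BED")
    invisible(path)
}

#' @rdname writeBed
#' @export
readBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    mcols(gr) <- NULL
    gr
}

#' Read and write per-window depth tracks as bedGraph
#'
#' mosdepth-style windowed depth (`chrom start end depth`) is bedGraph;
#' these wrappers attach/strip the [CoverageTrack-class] structure.
#'
#' @param track a `CoverageTrack`.
#' @param path file path.
#' @param sampleId,sex sample annotation to attach on read.
#' @return `readCoverageBed()` returns a `CoverageTrack`;
#'   `writeCoverageBed()` returns `path` invisibly.
#' @export
writeCoverageBed <- function(track, path) {
    gr <- windows(track)
    mcols(gr) <- NULL
    gr$score <- depth(track)
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

#' @rdname writeCoverageBed
#' @export
readCoverageBed <- function(path, sampleId, sex = "unknown") {
    gr <- rtracklayer::import(path, format = "bedGraph")
    d <- gr$score
    mcols(gr) <- NULL
    coverageTrack(gr, d, sampleId, sex)
}

#' Read a sample sheet for coverage tracks
#'
#' A sample sheet is a TSV with columns `sample_id`, `sex`, `path` giving
#' one windowed-depth bedGraph per sexed sample.
#'
#' @param path sample sheet TSV.
#' @param dir optional directory against which relative `path` entries are
#'   resolved.
#' @return named list of [CoverageTrack-class] objects.
#' @export
readSampleSheet <- function(path, dir = dirname(path)) {
    sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "sex", "path")
    if (!all(need %in% names(sheet)))
        stop("sample sheet must have columns: ", paste(need, collapse = ", "),
             call. = FALSE)
    tracks <- lapply(seq_len(nrow(sheet)), function(i) {
        p <- sheet$path[i]
        if (!file.exists(p)) p <- file.path(dir, p)
        readCoverageBed(p, sheet$sample_id[i], sheet$sex[i])
    })
    names(tracks) <- sheet$sample_id
    tracks
}
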