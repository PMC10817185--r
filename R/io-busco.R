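#' Read ortholog marker placements from a BUSCO full table
#'
#' Parses the tab-separated "full table" written by BUSCO in genome mode
#' (columns: busco id, status, sequence, gene start, gene end, ...;
#' comment lines start with `#`). Rows with status `Missing` carry no
#' coordinates and yield no marker; `Duplicated` ids yield one marker per
#' placement. Coordinates in the table are 1-based inclusive and are kept
#' as such in the returned `GRanges`.
#'
#' @param path path to a BUSCO full table TSV.
#' @return `GRanges` of markers with metadata columns `markerId` and
#'   `status` (lower-case: complete, duplicated, fragmented).
#' @examples
#' tf <- tempfile()
#' writeLines(c("# BUSCO results",
#'   "idA\tComplete\tchr1\t1000\t2000\t+\t99.1\t500",
#'   "idB\tMissing"), tf)
#' readBuscoMarkers(tf)
#' @export
readBuscoMarkers <- function(path) {
    lines <- readLines(path)
    keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
    lineNo <- which(keep)
    lines <- lines[keep]
    emptyMarkers <- function() {
        gr <- GRanges()
        mcols(gr) <- S4Vectors::DataFrame(markerId = character(),
                                          status = character())
        gr
    }
    if (length(lines) == 0L)
        return(emptyMarkers())
    fields <- strsplit(lines, "\t", fixed = TRUE)

    recs <- vector("list", length(fields))
    for (i in seq_along(fields)) {
        f <- fields[[i]]
        if (length(f) < 2L)
            stop("malformed BUSCO full-table row at line ", lineNo[i],
                 call. = FALSE)
        status <- tolower(f[2L])
        if (!status %in% c("complete", "duplicated", "fragmented", "missing"))
            stop("unknown BUSCO status '", f[2L], "' at line ", lineNo[i],
                 call. = FALSE)
        if (status == "missing")
            next
        if (length(f) < 5L)
            stop("malformed BUSCO full-table row at line ", lineNo[i],
                 ": placed marker lacks coordinates", call. = FALSE)
        st <- suppressWarnings(as.numeric(f[4L]))
        en <- suppressWarnings(as.numeric(f[5L]))
        if (is.na(st) || is.na(en) || en < st)
            stop("malformed coordinates in BUSCO full-table row at line ",
                 lineNo[i], call. = FALSE)
        recs[[i]] <- data.frame(markerId = f[1L], status = status,
                                chrom = f[3L], start = st, end = en,
                                stringsAsFactors = FALSE)
    }
    recs <- recs[!vapply(recs, is.null, logical(1))]
    if (length(recs) == 0L)
        return(emptyMarkers())
    df <- do.call(rbind, recs)
    GRanges(df$chrom, IRanges(df$start, df$end),
            markerId = df$markerId, status = df$status)
}

#' Read a marker-to-Nigon-element assignment table
#'
#' The map is a TSV with header `busco_id` and `nigon`, assigning each
#' ortholog marker to one of the seven ancestral Nigon elements
#' (A, B, C, D, E, N, X).
#'
#' @param path path to the map TSV.
#' @return named character vector: marker id -> element.
#' @export
readNigonMap <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("busco_id", "nigon") %in% names(df)))
        stop("Nigon map must have columns 'busco_id' and 'nigon'",
             call. = FALSE)
    bad <- setdiff(unique(df$nigon), NIGON_ELEMENTS)
    if (length(bad))
        stop("Nigon map contains elements outside the A-E, N, X alphabet: ",
             paste(bad, collapse = ", "), call. = FALSE)
    if (anyDuplicated(df$busco_id))
        stop("Nigon map assigns some marker ids more than once", call. = FALSE)
    stats::setNames(df$nigon, df$busco_id)
}
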