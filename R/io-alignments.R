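#' Read a one-to-one whole-genome alignment table
#'
#' Reads a tabular summary of genome alignments (e.g. derived from
#' NUCmer/delta-filter output) with header columns `query`, `target`,
#' `tstart`, `tend`, `length`, `identity`, `one_to_one`. Coordinates are
#' 0-based half-open on disk (so `length = tend - tstart`). Alignment
#' filtering follows the Y-contig analysis: only alignments at least
#' `minLength` bp long (1 kb by default, boundary inclusive) and, when
#' `requireOneToOne` is set, flagged one-to-one, are retained.
#'
#' @param path path to the alignment TSV.
#' @param minLength minimum alignment length in bp (inclusive).
#' @param requireOneToOne drop alignments not flagged one-to-one.
#' @return data.frame with columns `queryId`, `targetId`, `tstart`,
#'   `tend` (0-based half-open), `length`, `identity` (percent),
#'   `oneToOne`.
#' @seealso [ycontigCoverage()], [weightedIdentity()]
#' @export
readAlignments <- function(path, minLength = 1000, requireOneToOne = TRUE) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("query", "target", "tstart", "tend", "length", "identity",
              "one_to_one")
    if (!all(need %in% names(df)))
        stop("alignment table must have columns: ",
             paste(need, collapse = ", "), call. = FALSE)
    if (nrow(df) == 0L)
        return(data.frame(queryId = character(), targetId = character(),
                          tstart = numeric(), tend = numeric(),
                          length = numeric(), identity = numeric(),
                          oneToOne = logical()))
    if (any(df$identity < 0 | df$identity > 100))
        stop("alignment identity outside [0, 100]", call. = FALSE)
    if (any(df$tend - df$tstart <= 0))
        stop("alignment records must satisfy tend > tstart", call. = FALSE)
    if (any(df$length != df$tend - df$tstart))
        stop("alignment length must equal tend - tstart", call. = FALSE)
    oneToOne <- as.logical(df$one_to_one)
    keep <- df$length >= minLength
    if (requireOneToOne) keep <- keep & oneToOne
    out <- data.frame(queryId = df$query, targetId = df$target,
                      tstart = df$tstart, tend = df$tend,
                      length = df$length, identity = df$identity,
                      oneToOne = oneToOne, stringsAsFactors = FALSE)
    out[keep, , drop = FALSE]
}

## alignment table -> GRanges on the target genome (1-based internal)
alignmentRanges <- function(alignments) {
    GRanges(alignments$targetId,
            IRanges(alignments$tstart + 1, alignments$tend),
            identity = alignments$identity,
            alnLength = alignments$length)
}
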