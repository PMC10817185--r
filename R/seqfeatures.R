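#' Count telomere repeat motifs in windows
#'
#' Counts non-overlapping occurrences (greedy, left to right) of the
#' telomere motif and of its reverse complement in fixed windows
#' (nominal 1 kb) along a sequence. Matching is case-insensitive, so
#' softmasked arrays are counted; an occurrence is assigned to the window
#' containing its first base. Counting both strands makes chromosome-end
#' arrays detectable regardless of assembly orientation.
#'
#' @param seq a single sequence: character string or
#'   [Biostrings::DNAString].
#' @param motif DNA motif (default `"TTAGGC"`, the nematode telomere
#'   repeat).
#' @param windowSize window size in bp (default 1000).
#' @param chrom name used for the returned windows.
#' @return `GRanges` of windows with a `count` metadata column;
#'   `metadata()$motif` records the motif.
#' @export
telomereCounts <- function(seq, motif = "TTAGGC", windowSize = 1000,
                           chrom = "seq") {
    if (!nzchar(motif))
        stop("motif must be a non-empty DNA string", call. = FALSE)
    motif <- toupper(motif)
    if (grepl("[^ACGT]", motif))
        stop("motif must contain only A, C, G, T", call. = FALSE)
    s <- toupper(as.character(seq))
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif)))

    ## gregexpr with fixed = TRUE is exactly the greedy non-overlapping
    ## left-to-right scan
    hitStarts <- function(pat) {
        m <- gregexpr(pat, s, fixed = TRUE)[[1]]
        if (m[1] == -1L) integer() else as.integer(m)
    }
    starts <- hitStarts(motif)
    if (rc != motif) starts <- c(starts, hitStarts(rc))

    len <- nchar(s)
    w <- makeWindows(stats::setNames(len, chrom), windowSize)
    idx <- (starts - 1L) %/% as.integer(windowSize) + 1L
    w$count <- tabulate(idx, nbins = length(w))
    metadata(w)$motif <- motif
    w
}

#' Are chromosome ends capped by telomere arrays?
#'
#' Flags each end of a chromosome as telomere-capped when at least
#' `minCount` motif occurrences fall within `endSpan` bp of that end.
#'
#' @param track windowed counts from [telomereCounts()] covering the full
#'   chromosome.
#' @param endSpan span at each end to inspect, bp (default 10,000).
#' @param minCount minimum motif count to call an end capped.
#' @return named logical vector `c(left =, right =)`.
#' @export
endsCapped <- function(track, endSpan = 10000, minCount = 10) {
    chromLen <- max(end(track))
    if (endSpan > chromLen) {
        warning("endSpan exceeds chromosome length; evaluating on the ",
                "full sequence", call. = FALSE)
        endSpan <- chromLen
    }
    leftCount <- sum(track$count[start(track) <= endSpan])
    rightCount <- sum(track$count[end(track) > chromLen - endSpan])
    c(left = leftCount >= minCount, right = rightCount >= minCount)
}

#' Softmask repeat density in windows
#'
#' Fraction of softmasked (lowercase) bases per window (nominal 200 kb),
#' for sequences whose repeats were marked by a repeat finder that
#' lowercases repetitive sequence. Note that different repeat finders
#' mask very different proportions of the same genome (an any-repeat
#' finder can mask an order of magnitude more sequence than a
#' transposable-element annotator), so densities are comparable only
#' within one mask source.
#'
#' @param seq a single case-preserved sequence as a character string
#'   (see [readFastaMasked()]; `Biostrings` readers uppercase sequence
#'   and destroy the mask).
#' @param windowSize window size in bp (default 200,000).
#' @param chrom name used for the returned windows.
#' @return `GRanges` of windows with a `density` metadata column in
#'   `[0, 1]`.
#' @export
repeatDensity <- function(seq, windowSize = 200000, chrom = "seq") {
    s <- as.character(seq)
    raw <- charToRaw(s)
    isLower <- raw >= as.raw(97) & raw <= as.raw(122)
    len <- length(raw)
    w <- makeWindows(stats::setNames(len, chrom), windowSize)
    idx <- rep(seq_along(w), times = width(w))
    low <- tapply(as.integer(isLower), idx, sum)
    w$density <- as.numeric(low) / width(w)
    w
}

#' Read a FASTA file preserving softmask case
#'
#' Returns sequences as plain character strings with original case, for
#' use with [repeatDensity()].
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
readFastaMasked <- function(path) {
    seqs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
    stats::setNames(vapply(seqs, function(x) as.character(x)[1],
                           character(1)),
                    names(seqs))
}

#' Assembly summary metrics
#'
#' Span, sequence count, N50 and, when a consensus quality value (QV) is
#' supplied, the implied error spacing. N50 is the length of the shortest
#' sequence in the smallest descending-sorted prefix whose summed length
#' reaches half the span. QV is Phred-scaled base accuracy, so the
#' expected distance between consensus errors is `10^(QV/10)` bp.
#'
#' @param lengths numeric vector of sequence lengths in bp (non-empty,
#'   positive).
#' @param qv optional Phred-scaled consensus quality.
#' @return list with `spanBp`, `nSequences`, `n50Bp`, `qv`,
#'   `errorSpacingBp` (NULL when `qv` is not given).
#' @examples
#' assemblyMetrics(c(5, 3, 2))           # N50 = 5
#' assemblyMetrics(c(4, 4, 2), qv = 30)  # N50 = 4, 1 error per 1000 bp
#' @export
assemblyMetrics <- function(lengths, qv = NULL) {
    if (length(lengths) == 0L)
        stop("lengths must be non-empty", call. = FALSE)
    if (any(!is.finite(lengths)) || any(lengths <= 0))
        stop("all lengths must be positive", call. = FALSE)
    sorted <- sort(lengths, decreasing = TRUE)
    span <- sum(sorted)
    n50 <- sorted[which(cumsum(sorted) >= span / 2)[1]]
    spacing <- if (is.null(qv)) NULL else 10^(qv / 10)
    list(spanBp = span, nSequences = length(lengths), n50Bp = n50,
         qv = qv, errorSpacingBp = spacing)
}
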