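#' Assign painted ancestral elements to ortholog markers
#'
#' Labels each marker with its Nigon element from the assignment map;
#' markers absent from the map are labelled `"unassigned"`. Input order is
#' preserved and duplicated marker ids each receive the mapped element.
#' By default only complete and duplicated markers are painted;
#' fragmented placements are excluded (configurable via `statuses`).
#'
#' @param markers `GRanges` of markers from [readBuscoMarkers()].
#' @param map named character vector from [readNigonMap()].
#' @param statuses marker statuses eligible for painting.
#' @return `GRanges` like `markers` with an added `nigon` metadata
#'   column, restricted to `statuses`.
#' @export
assignNigon <- function(markers, map,
                        statuses = c("complete", "duplicated")) {
    keep <- markers$status %in% statuses
    painted <- markers[keep]
    el <- unname(map[painted$markerId])
    el[is.na(el)] <- "unassigned"
    painted$nigon <- el
    painted
}

#' Paint chromosomes in windows by ancestral element
#'
#' Counts painted markers per window and element; a marker is counted in
#' the window containing its start position. Markers on chromosomes
#' absent from the window grid are skipped with a warning and tallied in
#' the result's `nSkipped` slot.
#'
#' @param painted `GRanges` from [assignNigon()].
#' @param windows `GRanges` painting grid (nominal 500 kb windows).
#' @return A [NigonPaint-class] object.
#' @export
windowPaint <- function(painted, windows) {
    elements <- c(NIGON_ELEMENTS, "unassigned")
    counts <- matrix(0L, nrow = length(windows), ncol = length(elements),
                     dimnames = list(NULL, elements))
    nSkipped <- 0L
    if (length(painted)) {
        known <- as.character(seqnames(painted)) %in% seqlevels(windows)
        nSkipped <- sum(!known)
        if (nSkipped > 0L)
            warning(nSkipped,
                    " marker(s) on chromosomes absent from the window grid",
                    " were skipped", call. = FALSE)
        painted <- painted[known]
        if (length(painted)) {
            anchors <- GRanges(seqnames(painted),
                               IRanges(start(painted), width = 1L))
            GenomeInfoDb::seqlevels(anchors) <- seqlevels(windows)
            hits <- findOverlaps(anchors, windows)
            win <- subjectHits(hits)
            el <- painted$nigon[queryHits(hits)]
            tab <- table(factor(win, levels = seq_along(windows)),
                         factor(el, levels = elements))
            counts <- matrix(as.integer(tab), nrow = length(windows),
                             dimnames = list(NULL, elements))
        }
    }
    new("NigonPaint", windows = windows, counts = counts,
        nSkipped = as.integer(nSkipped))
}

#' Per-chromosome ancestral-element composition
#'
#' Sums painted-window counts per chromosome and reports, for each
#' chromosome, marker counts and fractions per element (fractions over
#' assigned markers) and the dominant element.
#'
#' @param paint a [NigonPaint-class] object.
#' @return data.frame with one row per chromosome: `chrom`, one count
#'   column per element, `unassigned`, `assigned` total, one `frac_*`
#'   column per element, and `dominant`.
#' @export
chromosomeComposition <- function(paint) {
    chroms <- as.character(seqnames(windows(paint)))
    counts <- paintCounts(paint)
    res <- lapply(unique(chroms), function(ch) {
        m <- counts[chroms == ch, , drop = FALSE]
        tot <- colSums(m)
        assigned <- sum(tot[NIGON_ELEMENTS])
        fr <- if (assigned > 0) tot[NIGON_ELEMENTS] / assigned
              else stats::setNames(rep(NA_real_, length(NIGON_ELEMENTS)),
                                   NIGON_ELEMENTS)
        dom <- if (assigned > 0) names(which.max(tot[NIGON_ELEMENTS]))
               else NA_character_
        cbind(data.frame(chrom = ch, stringsAsFactors = FALSE),
              as.data.frame(t(tot)),
              data.frame(assigned = assigned),
              stats::setNames(as.data.frame(t(fr)),
                              paste0("frac_", NIGON_ELEMENTS)),
              data.frame(dominant = dom, stringsAsFactors = FALSE))
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Detect fusion chromosomes from painted-marker composition
#'
#' Returns, for each chromosome, the set of ancestral elements that
#' contribute at least `minFraction` of its assigned markers and at least
#' `minCount` markers. A chromosome with two or more components is a
#' candidate fusion product. The defaults are chosen so that isolated
#' mis-assigned markers (stray colours on a painted chromosome) do not
#' trigger fusion calls.
#'
#' @param paint a [NigonPaint-class] object.
#' @param minFraction minimum fraction of assigned markers (default 0.05).
#' @param minCount minimum marker count (default 10).
#' @return named list: chromosome -> character vector of elements, sorted
#'   by decreasing marker count.
#' @export
detectFusions <- function(paint, minFraction = 0.05, minCount = 10) {
    comp <- chromosomeComposition(paint)
    unpaintable <- comp$chrom[comp$assigned == 0]
    if (length(unpaintable))
        stop("unpaintable chromosome (no assigned markers): ",
             paste(unpaintable, collapse = ", "), call. = FALSE)
    out <- lapply(seq_len(nrow(comp)), function(i) {
        cnt <- unlist(comp[i, NIGON_ELEMENTS])
        fr <- cnt / comp$assigned[i]
        el <- NIGON_ELEMENTS[fr >= minFraction & cnt >= minCount]
        el[order(cnt[el], decreasing = TRUE)]
    })
    stats::setNames(out, comp$chrom)
}

#' Runs test for intermixing of two ancestral-element partitions
#'
#' Quantifies whether markers from two elements along one chromosome are
#' blended or still partitioned, using the Wald-Wolfowitz runs framework.
#' With `n1` and `n2` markers of each element, the expected number of
#' runs under random arrangement is `1 + 2*n1*n2/(n1+n2)`; the z-score is
#' strongly negative when the two element partitions remain distinct
#' (few runs) and near zero when they are intermixed.
#'
#' @param labels character vector of element labels in marker order along
#'   the chromosome (positional order, ties broken by marker id); exactly
#'   two distinct labels must be present.
#' @return list with `n1`, `n2`, `runs`, `expectedRuns`, `zScore`, and a
#'   `verdict` (`"partitioned"` if z <= -1.96, `"intermixed"` if
#'   |z| < 1.96, `"alternating"` if z >= 1.96).
#' @examples
#' intermixingRuns(c("X", "X", "D", "D"))  # z = -1.22
#' @export
intermixingRuns <- function(labels) {
    labels <- as.character(labels)
    lev <- unique(labels)
    if (length(lev) != 2L)
        stop("runs undefined: exactly two element labels are required",
             call. = FALSE)
    n1 <- sum(labels == lev[1L])
    n2 <- sum(labels == lev[2L])
    runs <- length(rle(labels)$lengths)
    n <- n1 + n2
    expected <- 1 + 2 * n1 * n2 / n
    sigma2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
    if (sigma2 > 0) {
        z <- (runs - expected) / sqrt(sigma2)
        verdict <- if (z <= -1.96) "partitioned"
                   else if (z >= 1.96) "alternating"
                   else "intermixed"
    } else {
        ## degenerate case n1 = n2 = 1: the run count is constant
        z <- NA_real_
        verdict <- NA_character_
    }
    list(n1 = n1, n2 = n2, runs = runs, expectedRuns = expected,
         zScore = z, verdict = verdict)
}

#' Element labels of painted markers along one chromosome
#'
#' Helper producing the ordered label sequence consumed by
#' [intermixingRuns()]: markers on `chrom` restricted to `elements`,
#' ordered by start position with ties broken by marker id.
#'
#' @param painted `GRanges` from [assignNigon()].
#' @param chrom chromosome to inspect.
#' @param elements the two elements of interest (default: the two most
#'   frequent assigned elements on the chromosome).
#' @return character vector of element labels.
#' @export
elementSequence <- function(painted, chrom, elements = NULL) {
    onChrom <- painted[as.character(seqnames(painted)) == chrom &
                       painted$nigon != "unassigned"]
    if (is.null(elements)) {
        tab <- sort(table(onChrom$nigon), decreasing = TRUE)
        elements <- names(tab)[seq_len(min(2L, length(tab)))]
    }
    onChrom <- onChrom[onChrom$nigon %in% elements]
    ord <- order(start(onChrom), onChrom$markerId)
    onChrom$nigon[ord]
}

#' Pair single-copy markers placed in two painted genomes
#'
#' Builds the marker table behind pairwise synteny (Oxford) plots: one
#' row per marker that is complete and single-copy in both genomes, with
#' its position in each and its shared element label.
#'
#' @param paintedA,paintedB `GRanges` from [assignNigon()] for the two
#'   genomes, painted with the same Nigon map.
#' @return data.frame with columns `markerId`, `chromA`, `posA`,
#'   `chromB`, `posB`, `element`.
#' @export
syntenyPairs <- function(paintedA, paintedB) {
    singleCopy <- function(p) {
        p <- p[p$status == "complete"]
        p[!(p$markerId %in% p$markerId[duplicated(p$markerId)])]
    }
    a <- singleCopy(paintedA)
    b <- singleCopy(paintedB)
    shared <- intersect(a$markerId, b$markerId)
    ia <- match(shared, a$markerId)
    ib <- match(shared, b$markerId)
    out <- data.frame(markerId = shared,
                      chromA = as.character(seqnames(a))[ia],
                      posA = start(a)[ia],
                      chromB = as.character(seqnames(b))[ib],
                      posB = start(b)[ib],
                      element = a$nigon[ia],
                      stringsAsFactors = FALSE)
    out[order(out$chromA, out$posA), , drop = FALSE]
}
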