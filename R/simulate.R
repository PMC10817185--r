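#' SimulationConfig: study-condition parameters for synthetic fixtures
#'
#' Describes a simulated nematode karyotype and its genomic signals: the
#' seven ancestral element sizes, the fusion history that builds extant
#' chromosomes, post-fusion intermixing inversions, sexed sequencing
#' depth, the embryo-driven dilution of female X coverage, the neo-Y
#' geometry (the male-diploid shared region on the X, optional haploid
#' degeneration strata inside it, gametolog SNP rates) and telomere
#' caps.
#'
#' @slot elementsBp named numeric(7): bp per element (names A-E, N, X).
#' @slot markersPerElement numeric(1) ortholog markers per element.
#' @slot fusionHistory list of character vectors `c(a, b)` or
#'   `c(a, b, "-")`: each entry merges the chromosomes currently holding
#'   elements `a` and `b` (appending `b`'s blocks after `a`'s; a third
#'   entry `"-"` reverses the appended block order). Fusing two elements
#'   already on the same chromosome is an error.
#' @slot intermixInversions numeric(1) random internal inversions applied
#'   after fusion, restricted to the partition of `intermixElements`.
#' @slot intermixElements elements of the ancient fused partition that
#'   the inversions blend (default X and D).
#' @slot depthMean numeric(1) mean diploid depth, reads per base.
#' @slot depthDispersion numeric(1) negative-binomial size parameter of
#'   per-window read counts (larger = tighter).
#' @slot readLength numeric(1) bp per read, linking depth to read counts.
#' @slot embryoFraction numeric(1) in `[0, 1]`: fraction of female-sample
#'   DNA contributed by in-utero embryos (1:1 sex ratio), giving the
#'   female X a relative coverage of `1 - e/4`.
#' @slot sharedRegion numeric of length 0 or 2: 0-based half-open bp
#'   bounds of the male-diploid region on the X chromosome.
#' @slot strata list of numeric pairs (0-based half-open): haploid
#'   degeneration strata carved out of the shared region.
#' @slot snpRateShared numeric(1) heterozygous SNPs per bp inside the
#'   male-diploid span.
#' @slot boundaryMultiplier numeric(1): SNP rate multiplier in the bin
#'   immediately outside the shared-region start (0 = off).
#' @slot telomereRepeatsPerEnd numeric(1) telomere motif copies per
#'   chromosome end in emitted sequences.
#' @slot binSize numeric(1) coverage bin size in bp.
#' @slot seed numeric(1) base random seed.
#' @slot preset character(1) preset name, `""` for custom configs.
#' @seealso [presetConfig()], [buildKaryotype()], [writeFixtureSet()]
#' @export
setClass("SimulationConfig",
    representation(
        elementsBp = "numeric",
        markersPerElement = "numeric",
        fusionHistory = "list",
        intermixInversions = "numeric",
        intermixElements = "character",
        depthMean = "numeric",
        depthDispersion = "numeric",
        readLength = "numeric",
        embryoFraction = "numeric",
        sharedRegion = "numeric",
        strata = "list",
        snpRateShared = "numeric",
        boundaryMultiplier = "numeric",
        telomereRepeatsPerEnd = "numeric",
        binSize = "numeric",
        seed = "numeric",
        preset = "character"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (!identical(sort(names(object@elementsBp)), sort(NIGON_ELEMENTS)))
        msg <- c(msg, "elementsBp must be named with the seven elements A-E, N, X")
    if (any(object@elementsBp < 1))
        msg <- c(msg, "element sizes must be positive")
    if (object@embryoFraction < 0 || object@embryoFraction > 1)
        msg <- c(msg, "embryoFraction must lie in [0, 1]")
    if (!length(object@sharedRegion) %in% c(0L, 2L))
        msg <- c(msg, "sharedRegion must be empty or a (start, end) pair")
    if (length(object@sharedRegion) == 2L &&
        diff(object@sharedRegion) <= 0)
        msg <- c(msg, "sharedRegion end must exceed start")
    if (object@snpRateShared < 0 || object@boundaryMultiplier < 0)
        msg <- c(msg, "SNP rates must be >= 0")
    if (object@snpRateShared > 1 ||
        object@snpRateShared * max(1, object@boundaryMultiplier) > 1)
        msg <- c(msg, "SNP rates must not exceed 1 per bp")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig",
        if (nzchar(object@preset)) sprintf("('%s' preset)", object@preset),
        "\n")
    cat("  elements (Mb):",
        paste(sprintf("%s=%.2f", names(object@elementsBp),
                      object@elementsBp / 1e6), collapse = " "), "\n")
    cat("  fusions:",
        if (length(object@fusionHistory))
            paste(vapply(object@fusionHistory,
                         function(f) paste(f[1:2], collapse = "+"),
                         character(1)), collapse = ", ")
        else "none", "\n")
    cat("  depth:", object@depthMean, "x, embryo fraction:",
        object@embryoFraction, ", seed:", object@seed, "\n")
    if (length(object@sharedRegion))
        cat("  shared region:", formatBp(object@sharedRegion[1]), "-",
            formatBp(object@sharedRegion[2]), "bp on X\n")
})

#' TruthSet: ground truth of a simulated karyotype
#'
#' The fully resolved truth behind a set of synthetic fixtures: element
#' blocks of every chromosome after fusion and inversion, the X
#' chromosome, the planted shared region and strata, and the generating
#' config. Serialised to `truth.json` next to the fixtures.
#'
#' @slot blocks `GRanges` of element blocks with a `nigon` metadata
#'   column.
#' @slot chromLengths named numeric chromosome lengths.
#' @slot xChrom character(1) name of the X chromosome.
#' @slot sharedRegion `GRanges` (length 0 or 1) male-diploid region.
#' @slot strata `GRanges` haploid strata inside the shared region.
#' @slot config the generating [SimulationConfig-class].
#' @export
setClass("TruthSet",
    representation(
        blocks = "GRanges",
        chromLengths = "numeric",
        xChrom = "character",
        sharedRegion = "GRanges",
        strata = "GRanges",
        config = "SimulationConfig"
    )
)

setMethod("show", "TruthSet", function(object) {
    cat("TruthSet:", length(object@chromLengths), "chromosomes (",
        paste(names(object@chromLengths), collapse = ", "), ")\n")
    cat("  X:", object@xChrom, "\n")
    if (length(object@sharedRegion))
        cat("  shared region:", formatRegion(object@sharedRegion), "\n")
})

#' @export
setGeneric("trueKaryotype", function(x, ...) standardGeneric("trueKaryotype"))
#' @describeIn TruthSet-class element blocks accessor
#' @param x a `TruthSet`
#' @export
setMethod("trueKaryotype", "TruthSet", function(x) x@blocks)

## derived sub-seed, kept well below 2^31
subSeed <- function(seed, k) as.integer((seed * 97 + k) %% 2147483647L)

#' Preset simulation configurations for the four filarial architectures
#'
#' Ships the four studied karyotype architectures as ready-made configs:
#' \describe{
#'   \item{litomosoides}{5A + X, X0: one ancient X+D fusion, intermixed;
#'     no neo-Y, no shared region.}
#'   \item{dirofilaria}{4A + XY: X+D plus a recent X-autosome fusion with
#'     NigonE; the whole 15.2 Mb E partition is male-diploid (an intact
#'     neo-Y), SNP rate 1/2215 per bp.}
#'   \item{onchocerca}{3A + XY: as dirofilaria plus an A+N
#'     autosome-autosome fusion; only 3.4 Mb of the E partition remains
#'     male-diploid (degenerated neo-Y), SNP rate 1/314 per bp.}
#'   \item{brugia}{4A + XY: an independent X-autosome fusion with NigonN
#'     on a 25 Mb X; a 2.6 Mb male-diploid region in the N partition,
#'     SNP rate 1/2215 with a 7x elevated bin at the left boundary.}
#' }
#' Element sizes are chosen to reproduce the published chromosome and
#' region scales (e.g. the 25 Mb Brugia-like X and its
#' 22,300,000-24,943,668 shared region). Depth is 30x with 100 kb bins
#' and an embryo fraction of 0.8 for female samples.
#'
#' @param preset one of `"litomosoides"`, `"dirofilaria"`,
#'   `"onchocerca"`, `"brugia"`.
#' @param seed base random seed.
#' @param scale multiplier applied to all bp quantities (element sizes,
#'   shared region, strata, bin size); use small values for fast
#'   sequence-emitting fixtures.
#' @return A [SimulationConfig-class].
#' @examples
#' presetConfig("brugia", seed = 1)
#' @export
presetConfig <- function(preset = c("litomosoides", "dirofilaria",
                                    "onchocerca", "brugia"),
                         seed = 1, scale = 1) {
    preset <- match.arg(preset)
    base <- list(
        markersPerElement = 300,
        intermixInversions = 200,
        intermixElements = c("X", "D"),
        depthMean = 30,
        depthDispersion = 500,
        readLength = 150,
        embryoFraction = 0.8,
        strata = list(),
        boundaryMultiplier = 0,
        telomereRepeatsPerEnd = 50,
        binSize = 1e5
    )
    p <- switch(preset,
        litomosoides = list(
            elementsBp = c(A = 11e6, B = 11e6, C = 11e6, D = 5.5e6,
                           E = 11e6, N = 11e6, X = 5.5e6),
            fusionHistory = list(c("X", "D")),
            sharedRegion = numeric(),
            snpRateShared = 0),
        dirofilaria = list(
            elementsBp = c(A = 15e6, B = 15e6, C = 14.5e6, D = 6.5e6,
                           E = 15232375, N = 14e6, X = 6.5e6),
            fusionHistory = list(c("X", "D"), c("X", "E")),
            sharedRegion = c(13e6, 28232375),
            snpRateShared = 1 / 2215),
        onchocerca = list(
            elementsBp = c(A = 15e6, B = 15e6, C = 14.5e6, D = 6.5e6,
                           E = 15232375, N = 14e6, X = 6.5e6),
            fusionHistory = list(c("X", "D"), c("X", "E"), c("A", "N")),
            sharedRegion = c(22.1e6, 25485961),
            snpRateShared = 1 / 314),
        brugia = list(
            elementsBp = c(A = 14.7e6, B = 14e6, C = 13.6e6, D = 7e6,
                           E = 13.4e6, N = 11e6, X = 7e6),
            fusionHistory = list(c("X", "D"), c("X", "N")),
            sharedRegion = c(22.3e6, 24943668),
            snpRateShared = 1 / 2215,
            boundaryMultiplier = 7)
    )
    args <- utils::modifyList(base, p)
    args$elementsBp <- args$elementsBp * scale
    args$sharedRegion <- args$sharedRegion * scale
    args$strata <- lapply(args$strata, function(s) s * scale)
    args$binSize <- max(1, args$binSize * scale)
    new("SimulationConfig",
        elementsBp = args$elementsBp,
        markersPerElement = args$markersPerElement,
        fusionHistory = args$fusionHistory,
        intermixInversions = args$intermixInversions,
        intermixElements = args$intermixElements,
        depthMean = args$depthMean,
        depthDispersion = args$depthDispersion,
        readLength = args$readLength,
        embryoFraction = args$embryoFraction,
        sharedRegion = args$sharedRegion,
        strata = args$strata,
        snpRateShared = args$snpRateShared,
        boundaryMultiplier = args$boundaryMultiplier,
        telomereRepeatsPerEnd = args$telomereRepeatsPerEnd,
        binSize = args$binSize,
        seed = seed,
        preset = preset)
}

## fragment bookkeeping: a chromosome is a data.frame(element, len) in
## physical order; inversions split and reverse fragments
splitFragsAt <- function(frags, pos) {
    ## ensure a fragment boundary at 0-based offset pos
    ends <- cumsum(frags$len)
    starts <- ends - frags$len
    i <- which(starts < pos & ends > pos)
    if (length(i)) {
        left <- frags[seq_len(i - 1), , drop = FALSE]
        mid1 <- data.frame(element = frags$element[i],
                           len = pos - starts[i])
        mid2 <- data.frame(element = frags$element[i],
                           len = ends[i] - pos)
        right <- frags[-seq_len(i), , drop = FALSE]
        frags <- rbind(left, mid1, mid2, right)
    }
    frags
}

invertFragsWithin <- function(frags, span, nInversions) {
    for (k in seq_len(nInversions)) {
        bp <- sort(sample.int(span + 1, 2L) - 1L)
        if (bp[1] == bp[2]) next
        frags <- splitFragsAt(frags, bp[1])
        frags <- splitFragsAt(frags, bp[2])
        ends <- cumsum(frags$len)
        starts <- ends - frags$len
        mid <- which(starts >= bp[1] & ends <= bp[2])
        if (length(mid) > 1L)
            frags[mid, ] <- frags[rev(mid), ]
    }
    ## coalesce adjacent same-element fragments
    r <- rle(frags$element)
    grp <- rep(seq_along(r$lengths), r$lengths)
    data.frame(element = r$values,
               len = as.numeric(tapply(frags$len, grp, sum)))
}

#' Build a simulated karyotype from a fusion history
#'
#' Starts from seven single-element chromosomes, applies the fusion
#' history in order (each fusion merges the two chromosomes currently
#' holding the named elements; chromosome count is 7 minus the number of
#' fusions), then applies seeded random internal inversions restricted to
#' the ancient intermix partition of fused chromosomes, blending its
#' element blocks. The chromosome holding element X is named `chrX`;
#' other chromosomes are named by their element content (`chrA`,
#' `chrAN`, ...).
#'
#' @param config a [SimulationConfig-class].
#' @return A [TruthSet-class] with resolved element blocks, chromosome
#'   lengths, X identity, shared region and strata.
#' @export
buildKaryotype <- function(config) {
    set.seed(subSeed(config@seed, 0L))
    chroms <- lapply(names(config@elementsBp), function(el)
        data.frame(element = el, len = unname(config@elementsBp[el]),
                   stringsAsFactors = FALSE))
    holder <- function(el) {
        i <- which(vapply(chroms, function(ch) el %in% ch$element,
                          logical(1)))
        if (length(i) != 1L)
            stop("fusion history references unknown element '", el, "'",
                 call. = FALSE)
        i
    }
    for (f in config@fusionHistory) {
        ia <- holder(f[1]); ib <- holder(f[2])
        if (ia == ib)
            stop("elements ", f[1], " and ", f[2],
                 " are already on the same chromosome: ",
                 "an element cannot be fused twice", call. = FALSE)
        b <- chroms[[ib]]
        if (length(f) >= 3L && f[3] == "-")
            b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
        chroms[[ia]] <- rbind(chroms[[ia]], b)
        chroms <- chroms[-ib]
    }
    ## intermixing inversions within the ancient partition of fused chroms
    if (config@intermixInversions > 0) {
        for (i in seq_along(chroms)) {
            frags <- chroms[[i]]
            if (length(unique(frags$element)) < 2L) next
            prefix <- frags$element %in% config@intermixElements
            if (sum(prefix) < 2L) next
            nPrefix <- which(!prefix)[1] - 1L
            if (is.na(nPrefix)) nPrefix <- nrow(frags)
            if (nPrefix < 2L) next
            span <- sum(frags$len[seq_len(nPrefix)])
            chroms[[i]] <- invertFragsWithin(frags, span,
                                             config@intermixInversions)
        }
    }
    nameOf <- function(frags) {
        els <- unique(frags$element)
        if ("X" %in% els) "chrX"
        else paste0("chr", paste(sort(els), collapse = ""))
    }
    chromNames <- vapply(chroms, nameOf, character(1))
    names(chroms) <- chromNames
    lens <- vapply(chroms, function(ch) sum(ch$len), numeric(1))

    blockDf <- do.call(rbind, lapply(chromNames, function(nm) {
        frags <- chroms[[nm]]
        ends <- cumsum(frags$len)
        data.frame(chrom = nm, start = ends - frags$len + 1, end = ends,
                   element = frags$element, stringsAsFactors = FALSE)
    }))
    blocks <- GRanges(blockDf$chrom,
                      IRanges(blockDf$start, blockDf$end),
                      nigon = blockDf$element,
                      seqinfo = Seqinfo(chromNames,
                                        as.integer(lens)))

    xChrom <- "chrX"
    si <- GenomeInfoDb::seqinfo(blocks)
    shared <- GRanges(seqinfo = si)
    if (length(config@sharedRegion) == 2L) {
        shared <- GRanges(xChrom, IRanges(config@sharedRegion[1] + 1,
                                          config@sharedRegion[2]),
                          seqinfo = si)
        ## the planted region must lie in the ancestrally autosomal
        ## (recently fused, non-intermixed) partition of the X
        xBlocks <- blocks[seqnames(blocks) == xChrom &
                          !(blocks$nigon %in% config@intermixElements)]
        if (length(xBlocks) == 0L ||
            !all(overlapsAny(shared, reduce(granges(xBlocks)),
                             type = "within")))
            stop("sharedRegion must lie within the ancestrally autosomal ",
                 "partition of the fused X", call. = FALSE)
    }
    strata <- GRanges(seqinfo = si)
    if (length(config@strata)) {
        strata <- GRanges(rep(xChrom, length(config@strata)),
                          IRanges(vapply(config@strata, `[`, 0, 1) + 1,
                                  vapply(config@strata, `[`, 0, 2)),
                          seqinfo = si)
        if (length(shared) &&
            !all(overlapsAny(strata, shared, type = "within")))
            stop("degeneration strata must lie within the shared region",
                 call. = FALSE)
    }
    new("TruthSet", blocks = blocks, chromLengths = lens,
        xChrom = xChrom, sharedRegion = shared, strata = strata,
        config = config)
}

#' Place ortholog markers and emit painting inputs for a simulated genome
#'
#' `placeMarkers()` scatters `markersPerElement` markers uniformly over
#' each element's blocks (post-inversion, so the marker order along a
#' blended chromosome reflects the inversion history) and returns them
#' with their true element. `emitGenomeAndMarkers()` additionally builds
#' the chromosome sequences: random nucleotides with
#' `telomereRepeatsPerEnd` copies of the telomere motif TTAGGC at the
#' left end and of its reverse complement at the right end.
#'
#' @param truth a [TruthSet-class] from [buildKaryotype()].
#' @return `placeMarkers()`: `GRanges` of markers with `markerId`,
#'   `status` (all `"complete"`) and `nigon` metadata columns.
#'   `emitGenomeAndMarkers()`: list with `genome`
#'   ([Biostrings::DNAStringSet]), `markers`, and `nigonMap` (named
#'   character vector).
#' @export
placeMarkers <- function(truth) {
    config <- truth@config
    set.seed(subSeed(config@seed, 1L))
    m <- as.integer(config@markersPerElement)
    blocks <- truth@blocks
    counter <- 0L
    out <- lapply(NIGON_ELEMENTS, function(el) {
        frags <- blocks[blocks$nigon == el]
        totalBp <- sum(width(frags))
        if (m > totalBp)
            stop("marker count exceeds bp capacity of element ", el,
                 call. = FALSE)
        offs <- sort(sample.int(totalBp, m))
        cumEnd <- cumsum(width(frags))
        fi <- findInterval(offs - 1L, c(0, cumEnd), rightmost.closed = TRUE)
        local <- offs - c(0, cumEnd)[fi]
        pos <- start(frags)[fi] + local - 1L
        ids <- sprintf("%06dat6231", counter + seq_len(m))
        counter <<- counter + m
        data.frame(chrom = as.character(seqnames(frags))[fi],
                   start = pos,
                   end = pos + pmin(1000L, end(frags)[fi] - pos + 1L) - 1L,
                   markerId = ids, nigon = el,
                   stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, out)
    markers <- GRanges(df$chrom, IRanges(df$start, df$end),
                       markerId = df$markerId, status = "complete",
                       nigon = df$nigon,
                       seqinfo = GenomeInfoDb::seqinfo(blocks))
    sort(markers)
}

#' @rdname placeMarkers
#' @export
emitGenomeAndMarkers <- function(truth) {
    config <- truth@config
    markers <- placeMarkers(truth)
    set.seed(subSeed(config@seed, 2L))
    k <- as.integer(config@telomereRepeatsPerEnd)
    teloL <- strrep("TTAGGC", k)
    teloR <- strrep("GCCTAA", k)
    seqs <- vapply(names(truth@chromLengths), function(nm) {
        len <- as.integer(truth@chromLengths[nm])
        body <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                      collapse = "")
        if (len > 2L * nchar(teloL))
            body <- paste0(teloL,
                           substr(body, nchar(teloL) + 1L,
                                  len - nchar(teloR)),
                           teloR)
        body
    }, character(1))
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- names(truth@chromLengths)
    nigonMap <- stats::setNames(markers$nigon, markers$markerId)
    list(genome = genome, markers = markers, nigonMap = nigonMap)
}

## per-window expected relative coverage (1 = diploid autosome)
windowPloidyFactor <- function(truth, sex, w) {
    config <- truth@config
    onX <- as.character(seqnames(w)) == truth@xChrom
    factor <- rep(1, length(w))
    if (sex == "female") {
        factor[onX] <- 1 - config@embryoFraction / 4
    } else {
        mids <- (start(w) + end(w)) / 2
        midPts <- GRanges(seqnames(w), IRanges(round(mids), width = 1L))
        diploidX <- overlapsAny(midPts, truth@sharedRegion) &
            !overlapsAny(midPts, truth@strata)
        factor[onX] <- ifelse(diploidX[onX], 1, 0.5)
    }
    factor
}

#' Simulate a sexed windowed coverage track
#'
#' Draws per-window read counts from a negative binomial with mean
#' proportional to local copy number and converts them to mean per-base
#' depth. Autosomes are diploid in both sexes. The male X is haploid
#' (expected N = 0.5) except inside the shared region minus any
#' degeneration strata, where the neo-Y copy restores diploid coverage
#' (N = 1). The female X is diluted by embryo DNA: with embryo fraction
#' `e` and a 1:1 embryo sex ratio its expected relative coverage is
#' `1 - e/4` (0.8 at the default `e = 0.8`).
#'
#' @param truth a [TruthSet-class].
#' @param sex `"male"` or `"female"`.
#' @param seedOffset integer added to the derived seed, so several
#'   replicate samples per sex can be drawn.
#' @return A [CoverageTrack-class] on the config's bin grid.
#' @export
simulateCoverage <- function(truth, sex, seedOffset = 0L) {
    if (!sex %in% c("male", "female"))
        stop("sex must be 'male' or 'female'", call. = FALSE)
    config <- truth@config
    set.seed(subSeed(config@seed, 3L + seedOffset +
                         ifelse(sex == "male", 0L, 1000L)))
    w <- makeWindows(truth@chromLengths, config@binSize)
    factor <- windowPloidyFactor(truth, sex, w)
    muReads <- config@depthMean * factor * width(w) / config@readLength
    reads <- stats::rnbinom(length(w), mu = muReads,
                            size = config@depthDispersion)
    depth <- reads * config@readLength / width(w)
    coverageTrack(w, depth, paste0("sim_", sex), sex)
}

#' Simulate male heterozygous gametolog SNPs
#'
#' Plants Poisson-distributed heterozygous SNPs at rate `snpRateShared`
#' per bp uniformly over the male-diploid span (the shared region minus
#' degeneration strata), at `snpRateShared * boundaryMultiplier` in the
#' bin immediately outside the shared-region start (the elevated
#' neighbouring-stratum signal), and nowhere else.
#'
#' @param truth a [TruthSet-class].
#' @param seedOffset integer added to the derived seed.
#' @return `GRanges` of SNP positions with `ref`/`alt` metadata columns
#'   and `metadata()$sampleId = "sim_male"`.
#' @export
simulateSnps <- function(truth, seedOffset = 0L) {
    config <- truth@config
    set.seed(subSeed(config@seed, 5L + seedOffset))
    spans <- GRanges()
    rates <- numeric()
    if (length(truth@sharedRegion) && config@snpRateShared > 0) {
        diploid <- setdiff(truth@sharedRegion, truth@strata)
        spans <- diploid
        rates <- rep(config@snpRateShared, length(diploid))
        if (config@boundaryMultiplier > 0) {
            bStart <- max(1, start(truth@sharedRegion) - config@binSize)
            boundary <- GRanges(truth@xChrom,
                                IRanges(bStart,
                                        start(truth@sharedRegion) - 1))
            if (width(boundary) > 0) {
                spans <- c(spans, boundary)
                rates <- c(rates,
                           config@snpRateShared * config@boundaryMultiplier)
            }
        }
    }
    bases <- c("A", "C", "G", "T")
    snpList <- lapply(seq_along(spans), function(i) {
        wspan <- width(spans)[i]
        n <- stats::rpois(1, rates[i] * wspan)
        n <- min(n, wspan)
        if (n == 0L) return(GRanges())
        pos <- start(spans)[i] + sort(sample.int(wspan, n)) - 1L
        ref <- sample(bases, n, replace = TRUE)
        alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                      character(1))
        GRanges(as.character(seqnames(spans))[i], IRanges(pos, width = 1L),
                ref = ref, alt = unname(alt))
    })
    snps <- if (length(snpList)) do.call(c, snpList) else GRanges()
    if (length(snps) == 0L)
        mcols(snps) <- S4Vectors::DataFrame(ref = character(),
                                            alt = character())
    snps <- sort(snps)
    GenomeInfoDb::seqlevels(snps) <- names(truth@chromLengths)
    seqlengths(snps) <- truth@chromLengths
    metadata(snps)$sampleId <- "sim_male"
    snps
}

#' Write a complete synthetic fixture set to disk
#'
#' Runs the whole generator for a config and writes the fixture files
#' every pipeline stage consumes: `genome.fa` (optional), BUSCO-style
#' `busco_full_table.tsv`, `nigon_map.tsv`, sexed windowed-depth tracks
#' `cov_male.bed` / `cov_female.bed` (bedGraph), `snps_male.vcf` and the
#' serialised ground truth `truth.json`. Output is deterministic: the
#' same config and seed reproduce byte-identical files; a checksum
#' manifest is returned for verification.
#'
#' @param config a [SimulationConfig-class].
#' @param outdir output directory (created if needed).
#' @param sequences also emit `genome.fa` (skip for large karyotypes
#'   where only tracks are needed).
#' @return data.frame manifest with columns `file` and `md5`, invisibly
#'   returned along with the paths; also returns the `TruthSet` in the
#'   `truth` attribute.
#' @export
writeFixtureSet <- function(config, outdir, sequences = TRUE) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    truth <- buildKaryotype(config)

    if (sequences) {
        gm <- emitGenomeAndMarkers(truth)
        Biostrings::writeXStringSet(gm$genome, file.path(outdir, "genome.fa"),
                                    width = 80L)
        markers <- gm$markers
    } else {
        markers <- placeMarkers(truth)
    }

    busco <- c("# Synthetic BUSCO full table",
               sprintf("%s\tComplete\t%s\t%d\t%d\t+\t100.0\t%d",
                       markers$markerId, as.character(seqnames(markers)),
                       start(markers), end(markers), width(markers)))
    writeLines(busco, file.path(outdir, "busco_full_table.tsv"))

    writeLines(c("busco_id\tnigon",
                 sprintf("%s\t%s", markers$markerId, markers$nigon)),
               file.path(outdir, "nigon_map.tsv"))

    covM <- simulateCoverage(truth, "male")
    covF <- simulateCoverage(truth, "female")
    writeCoverageBed(covM, file.path(outdir, "cov_male.bed"))
    writeCoverageBed(covF, file.path(outdir, "cov_female.bed"))

    snps <- simulateSnps(truth)
    writeHetSnpsVcf(snps, file.path(outdir, "snps_male.vcf"),
                    sampleId = "sim_male",
                    chromLengths = truth@chromLengths)

    truthJson <- list(
        preset = config@preset,
        seed = config@seed,
        binSize = config@binSize,
        chromLengths = as.list(truth@chromLengths),
        xChrom = truth@xChrom,
        karyotype = data.frame(
            chrom = as.character(seqnames(truth@blocks)),
            start0 = start(truth@blocks) - 1,
            end0 = end(truth@blocks),
            element = truth@blocks$nigon),
        fusionComponents = lapply(
            split(truth@blocks$nigon,
                  as.character(seqnames(truth@blocks))),
            function(e) sort(unique(e))),
        sharedRegion = if (length(truth@sharedRegion))
            list(chrom = truth@xChrom,
                 start0 = start(truth@sharedRegion) - 1,
                 end0 = end(truth@sharedRegion))
            else NULL,
        strata = if (length(truth@strata))
            data.frame(start0 = start(truth@strata) - 1,
                       end0 = end(truth@strata))
            else NULL,
        snpRateShared = config@snpRateShared,
        boundaryMultiplier = config@boundaryMultiplier,
        embryoFraction = config@embryoFraction,
        depthMean = config@depthMean)
    jsonlite::write_json(truthJson, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    files <- c(if (sequences) "genome.fa", "busco_full_table.tsv",
               "nigon_map.tsv", "cov_male.bed", "cov_female.bed",
               "snps_male.vcf", "truth.json")
    manifest <- data.frame(
        file = files,
        md5 = unname(tools::md5sum(file.path(outdir, files))),
        stringsAsFactors = FALSE)
    attr(manifest, "truth") <- truth
    invisible(manifest)
}
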