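## Independent brute-force oracles and small fixture builders shared by
## the unit and acceptance tests.

## --- runs statistic oracle: mean run count over every distinct ordering
## of a two-element multiset (n1 + n2 small) ---
enumerateMeanRuns <- function(n1, n2) {
    n <- n1 + n2
    positions <- utils::combn(n, n1)
    runs <- apply(positions, 2, function(pos) {
        x <- rep("b", n)
        x[pos] <- "a"
        length(rle(x)$lengths)
    })
    mean(runs)
}

## --- shared-region caller oracle ---
## classes: vector in {"q","f","m"} on a uniform grid of binSize bp bins.
## Enumerates every candidate interval [i, j] with qualifying endpoints,
## checks that each internal maximal non-qualifying run spans <= mergeGap
## and that the interval is >= minLen long, then keeps the maximal ones.
## Returns a data.frame(startBin, endBin), possibly empty.
oracleSharedRegions <- function(classes, binSize, mergeGap, minLen) {
    n <- length(classes)
    valid <- list()
    for (i in seq_len(n)) {
        if (classes[i] != "q") next
        for (j in i:n) {
            if (classes[j] != "q") next
            inner <- if (j > i + 1) classes[(i + 1):(j - 1)] else character()
            ok <- TRUE
            if (length(inner)) {
                r <- rle(inner != "q")
                if (any(r$lengths[r$values] * binSize > mergeGap))
                    ok <- FALSE
            }
            if (ok && (j - i + 1) * binSize >= minLen)
                valid[[length(valid) + 1]] <- c(i, j)
        }
    }
    if (!length(valid))
        return(data.frame(startBin = integer(), endBin = integer()))
    v <- do.call(rbind, valid)
    maximal <- vapply(seq_len(nrow(v)), function(k) {
        !any(v[, 1] <= v[k, 1] & v[, 2] >= v[k, 2] &
             (v[, 1] != v[k, 1] | v[, 2] != v[k, 2]))
    }, logical(1))
    v <- v[maximal, , drop = FALSE]
    v <- v[order(v[, 1]), , drop = FALSE]
    data.frame(startBin = v[, 1], endBin = v[, 2])
}

## run the installed caller on a raw classification vector
callerSharedRegions <- function(classes, binSize, mergeGap, minLen) {
    n <- length(classes)
    starts <- (seq_len(n) - 1) * binSize + 1
    ends <- seq_len(n) * binSize
    out <- karyoscope:::mergeSharedBins(classes, starts, ends,
                                        mergeGap, minLen)
    data.frame(startBin = as.integer((out$start - 1) / binSize + 1),
               endBin = as.integer(out$end / binSize))
}

## all classification vectors of length n over the given states
allClassVectors <- function(n, states) {
    grid <- do.call(expand.grid,
                    c(rep(list(states), n),
                      list(stringsAsFactors = FALSE)))
    lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ],
                                                   use.names = FALSE))
}

## --- N50 oracle: largest L among observed lengths such that sequences
## of length >= L sum to at least half the span ---
oracleN50 <- function(lengths) {
    span <- sum(lengths)
    cand <- sort(unique(lengths), decreasing = TRUE)
    for (L in cand)
        if (sum(lengths[lengths >= L]) >= span / 2) return(L)
    min(lengths)
}

## --- small fixture builders ---
makeTrack <- function(depths, chromLengths, binSize, sampleId = "s",
                      sex = "unknown") {
    w <- makeWindows(chromLengths, binSize)
    stopifnot(length(depths) == length(w))
    coverageTrack(w, depths, sampleId, sex)
}

writeTempLines <- function(lines) {
    tf <- tempfile()
    writeLines(lines, tf)
    tf
}
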