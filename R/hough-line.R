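#' Hough line accumulation over (theta, rho)
#'
#' Maps every edge pixel into the normal-parameterized line space: a pixel
#' at (row a, col b) votes, for each theta bin, for the rho bin nearest to
#' `rho = a cos(theta) + b sin(theta)`. A single pixel thus traces one
#' sinusoid through the accumulator (one vote per theta bin); collinear
#' pixels' sinusoids intersect in the bin of their common line.
#'
#' @param edgeMap an [EdgeMap-class] (or logical matrix).
#' @param nTheta number of theta bins over \[0, pi) (default 180, i.e. 1
#'   degree).
#' @param rhoRes rho bin width in px (default 1).
#' @return a [LineAccumulator-class]. An empty edge map yields an all-zero
#'   accumulator.
#' @export
houghLineAccumulate <- function(edgeMap, nTheta = 180L, rhoRes = 1) {
    E <- if (is(edgeMap, "EdgeMap")) edgeMap@edges else edgeMap
    .stopIf(nTheta < 1 || rhoRes <= 0, "need nTheta >= 1 and rhoRes > 0")
    nr <- nrow(E); nc <- ncol(E)
    theta <- (seq_len(nTheta) - 1) * pi / nTheta
    D <- ceiling(sqrt(nr^2 + nc^2) / rhoRes) * rhoRes
    rho <- seq(-D, D, by = rhoRes)
    acc <- matrix(0L, nTheta, length(rho))
    ep <- which(E, arr.ind = TRUE)
    if (nrow(ep)) {
        for (i in seq_len(nTheta)) {
            r <- ep[, 1] * cos(theta[i]) + ep[, 2] * sin(theta[i])
            j <- round((r + D) / rhoRes) + 1
            tb <- tabulate(j, nbins = length(rho))
            acc[i, ] <- acc[i, ] + as.integer(tb)
        }
    }
    new("LineAccumulator", votes = acc, theta = theta, rho = rho)
}

#' Extract line peaks from a Hough accumulator
#'
#' Greedy non-maximum suppression: bins are visited in order of decreasing
#' votes (ties broken by ascending theta then rho, so output is fully
#' deterministic); a bin is accepted if it is at least `nmsRadius` bins away
#' (Chebyshev distance, theta axis wrapping around) from every previously
#' accepted peak.
#'
#' @param acc a [LineAccumulator-class].
#' @param k maximum number of peaks.
#' @param minVotes minimum votes for a peak.
#' @param nmsRadius suppression radius in bins.
#' @return data.frame with columns `theta`, `rho`, `votes`, sorted by votes
#'   descending (ties: theta, rho ascending).
#' @export
houghLinePeaks <- function(acc, k = 4L, minVotes = 2L, nmsRadius = 5L) {
    stopifnot(is(acc, "LineAccumulator"))
    .stopIf(k < 1, "k must be >= 1")
    v <- acc@votes
    cand <- which(v >= minVotes, arr.ind = TRUE)
    empty <- data.frame(theta = numeric(), rho = numeric(), votes = integer())
    if (!nrow(cand)) return(empty)
    vv <- v[cand]
    ord <- order(-vv, cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    vv <- vv[ord]
    nTheta <- length(acc@theta)
    accIdx <- matrix(0L, 0, 2)
    out <- integer()
    for (i in seq_len(nrow(cand))) {
        if (nrow(accIdx)) {
            dt <- abs(accIdx[, 1] - cand[i, 1])
            dt <- pmin(dt, nTheta - dt)  # theta wraps at pi
            dr <- abs(accIdx[, 2] - cand[i, 2])
            if (any(pmax(dt, dr) < nmsRadius)) next
        }
        accIdx <- rbind(accIdx, cand[i, ])
        out <- c(out, i)
        if (length(out) >= k) break
    }
    data.frame(theta = acc@theta[cand[out, 1]],
               rho = acc@rho[cand[out, 2]],
               votes = as.integer(vv[out]))
}
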