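#' Midpoint-circle rasterization of a centre locus
#'
#' Integer offsets (da, db) of the midpoint (Bresenham) circle of radius
#' `r`: in the first octant `db = round(sqrt(r^2 - da^2))`, reflected to all
#' eight octants and de-duplicated. This exact integer geometry is what the
#' accumulator casts votes on, which is what makes brute-force comparison
#' of accumulators bin-for-bin exact.
#'
#' @param r radius in px (may be fractional).
#' @return integer matrix with columns `da`, `db`.
#' @export
circleOffsets <- function(r) {
    .stopIf(r <= 0, "radius must be positive")
    da <- 0:floor(r / sqrt(2))
    db <- round(sqrt(r^2 - da^2))
    oct <- cbind(da, db)
    pts <- rbind(oct,
                 cbind(oct[, 1], -oct[, 2]),
                 cbind(-oct[, 1], oct[, 2]),
                 cbind(-oct[, 1], -oct[, 2]),
                 oct[, 2:1],
                 cbind(oct[, 2], -oct[, 1]),
                 cbind(-oct[, 2], oct[, 1]),
                 cbind(-oct[, 2], -oct[, 1]))
    pts <- unique(pts)
    colnames(pts) <- c("da", "db")
    pts
}

#' Fill the 3-D Hough circle accumulator A(a, b, r)
#'
#' For every edge pixel and every candidate radius, votes are cast on the
#' locus of circle centres at that distance -- the rasterized circle around
#' the pixel. Across radii the votes from one pixel form a cone in the
#' (a, b, r) parameter space; true circle parameters accumulate one vote
#' per participating edge pixel where the cones intersect.
#'
#' Centre bins coincide with the pixel grid (1 px); radii run
#' `seq(rMin, rMax, rStep)`.
#'
#' @param edgeMap an [EdgeMap-class] (or logical matrix).
#' @param rMin,rMax radius search range in px, `0 < rMin <= rMax`.
#' @param rStep radius bin width (default 1 px).
#' @return a [CircleAccumulator-class].
#' @export
houghCircleAccumulate <- function(edgeMap, rMin, rMax, rStep = 1) {
    E <- if (is(edgeMap, "EdgeMap")) edgeMap@edges else edgeMap
    .stopIf(!(rMin > 0 && rMin <= rMax && rStep > 0),
            "need 0 < rMin <= rMax and rStep > 0")
    nr <- nrow(E); nc <- ncol(E)
    rBins <- seq(rMin, rMax, by = rStep)
    if (min(rBins) > sqrt(nr^2 + nc^2))
        warning("radius range excludes all image-feasible circles")
    votes <- array(0L, dim = c(nr, nc, length(rBins)))
    ep <- which(E, arr.ind = TRUE)
    perimeter <- numeric(length(rBins))
    for (k in seq_along(rBins)) {
        off <- circleOffsets(rBins[k])
        perimeter[k] <- nrow(off)
        if (!nrow(ep)) next
        a <- rep(ep[, 1], each = nrow(off)) + off[, 1]
        b <- rep(ep[, 2], each = nrow(off)) + off[, 2]
        ok <- a >= 1 & a <= nr & b >= 1 & b <= nc
        idx <- (b[ok] - 1L) * nr + a[ok]
        votes[, , k] <- votes[, , k] +
            matrix(as.integer(tabulate(idx, nbins = nr * nc)), nr, nc)
    }
    new("CircleAccumulator", votes = votes,
        aBins = as.numeric(seq_len(nr)), bBins = as.numeric(seq_len(nc)),
        rBins = rBins, perimeter = perimeter)
}

#' Extract circle peaks from the 3-D accumulator
#'
#' Peaks are scored by votes normalized by the rasterized perimeter count
#' for their radius (the vote count a fully supported circle of that radius
#' would achieve), so large circles are not favoured merely for having more
#' boundary pixels. Greedy 3-D non-maximum suppression with a fully
#' deterministic order: candidates sorted by descending score, ties broken
#' lexicographically by ascending (a, b, r).
#'
#' @param acc a [CircleAccumulator-class].
#' @param k maximum number of circles.
#' @param minVotes minimum raw votes for a candidate bin.
#' @param nmsRadius suppression radius in bins (Chebyshev, all three axes).
#' @return data.frame with columns `a`, `b`, `r`, `votes`, `score`, sorted
#'   by score descending.
#' @export
houghCirclePeaks <- function(acc, k = 4L, minVotes = 8L, nmsRadius = 5L) {
    stopifnot(is(acc, "CircleAccumulator"))
    .stopIf(k < 1, "k must be >= 1")
    v <- acc@votes
    cand <- which(v >= max(minVotes, 1L), arr.ind = TRUE)
    empty <- data.frame(a = numeric(), b = numeric(), r = numeric(),
                        votes = integer(), score = numeric())
    if (!nrow(cand)) return(empty)
    vv <- v[cand]
    score <- vv / acc@perimeter[cand[, 3]]
    ord <- order(-score, cand[, 1], cand[, 2], cand[, 3])
    cand <- cand[ord, , drop = FALSE]
    vv <- vv[ord]; score <- score[ord]
    sel <- integer()
    accIdx <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(cand))) {
        if (nrow(accIdx)) {
            d <- pmax(abs(accIdx[, 1] - cand[i, 1]),
                      abs(accIdx[, 2] - cand[i, 2]),
                      abs(accIdx[, 3] - cand[i, 3]))
            if (any(d < nmsRadius)) next
        }
        accIdx <- rbind(accIdx, cand[i, ])
        sel <- c(sel, i)
        if (length(sel) >= k) break
    }
    data.frame(a = acc@aBins[cand[sel, 1]],
               b = acc@bBins[cand[sel, 2]],
               r = acc@rBins[cand[sel, 3]],
               votes = as.integer(vv[sel]),
               score = score[sel])
}

#' Sub-pixel refinement of a circle centre and radius
#'
#' Refines a coarse (integer-bin) Hough detection to sub-pixel precision.
#' The centre is updated as the intensity-weighted centroid of the annulus
#' neighbourhood: pixels within `window` px of the current radius, weighted
#' by intensity above the local background (the minimum intensity in the
#' band). The radius is updated as the gradient-magnitude-weighted mean
#' distance of the band pixels from the centre -- standard sub-pixel edge
#' localization, which is unbiased for both annular and filled (disc)
#' markers because the gradient profile is symmetric about each edge.
#' Both updates are iterated to a fixed point; the refined centre is
#' clamped to at most 1.5 px and the radius to 2 px from the coarse bin.
#'
#' @param image the [ImageSlice-class] (or matrix) the circle was detected
#'   in.
#' @param a,b,r coarse centre (row, col) and radius in px.
#' @param window half-width of the annulus band in px (default 2.5).
#' @param iterations refinement iterations (default 5).
#' @return list with `a`, `b`, `r` (refined, sub-pixel) and `clipped`
#'   (TRUE if the annulus window extended outside the image and was
#'   clipped).
#' @export
refineCenter <- function(image, a, b, r, window = 2.5, iterations = 5L) {
    if (is(image, "ImageSlice")) image <- image@intensity
    nr <- nrow(image); nc <- ncol(image)
    .stopIf(a < 1 || a > nr || b < 1 || b > nc,
            "coarse centre (%.1f, %.1f) outside the image", a, b)
    a0 <- a; b0 <- b; r0 <- r
    ## gradient magnitude for the radius update (plain central differences)
    gr <- gc <- matrix(0, nr, nc)
    gr[2:(nr - 1), ] <- (image[3:nr, ] - image[1:(nr - 2), ]) / 2
    gc[, 2:(nc - 1)] <- (image[, 3:nc] - image[, 1:(nc - 2)]) / 2
    gmag <- sqrt(gr^2 + gc^2)
    ext <- r + window + 2
    clipped <- (a - ext < 1) || (a + ext > nr) || (b - ext < 1) || (b + ext > nc)
    bandData <- function(a, b, r) {
        ext <- r + window + 1
        rlo <- max(1, floor(a - ext)); rhi <- min(nr, ceiling(a + ext))
        clo <- max(1, floor(b - ext)); chi <- min(nc, ceiling(b + ext))
        R <- matrix(rlo:rhi, rhi - rlo + 1, chi - clo + 1)
        C <- matrix(clo:chi, rhi - rlo + 1, chi - clo + 1, byrow = TRUE)
        d <- sqrt((R - a)^2 + (C - b)^2)
        list(R = R, C = C, d = d, band = abs(d - r) <= window,
             sub = image[rlo:rhi, clo:chi, drop = FALSE],
             g = gmag[rlo:rhi, clo:chi, drop = FALSE])
    }
    ## settle the radius first (with the centre held at the coarse bin):
    ## an off-radius band clips the marker's outer skirt asymmetrically and
    ## would bias the centre centroid
    for (it in seq_len(iterations + 2L)) {
        bd <- bandData(a, b, r)
        wg <- bd$g; wg[!bd$band] <- 0
        if (sum(wg) <= 0) break
        rNew <- min(max(sum(wg * bd$d) / sum(wg), r0 - 2.5), r0 + 2.5)
        if (abs(rNew - r) < 1e-4) { r <- rNew; break }
        r <- rNew
    }
    ## then iterate the centre centroid (and keep the radius in step)
    for (it in seq_len(iterations)) {
        bd <- bandData(a, b, r)
        if (!any(bd$band)) break
        w <- bd$sub - min(bd$sub[bd$band])
        w[!bd$band] <- 0
        sw <- sum(w)
        if (sw <= 0) break
        a <- sum(w * bd$R) / sw
        b <- sum(w * bd$C) / sw
        ## stay within 1.5 px of the coarse centre
        da <- a - a0; db <- b - b0
        sh <- sqrt(da^2 + db^2)
        if (sh > 1.5) {
            a <- a0 + da * 1.5 / sh
            b <- b0 + db * 1.5 / sh
        }
        wg <- bd$g; wg[!bd$band] <- 0
        if (sum(wg) > 0)
            r <- min(max(sum(wg * bd$d) / sum(wg), r0 - 2.5), r0 + 2.5)
    }
    list(a = a, b = b, r = r, clipped = clipped)
}

#' Detect circular mark points in a slice
#'
#' Convenience pipeline: edge detection, circle Hough accumulation, peak
#' extraction, and sub-pixel centre refinement.
#'
#' @param image an [ImageSlice-class] or matrix.
#' @param rMin,rMax,rStep radius search range (px).
#' @param k maximum number of circles.
#' @param low,high,sigma edge-detector settings, see [detectEdges()].
#' @param minVotes,nmsRadius peak settings, see [houghCirclePeaks()].
#' @param refine logical; add sub-pixel refined centres (default TRUE).
#' @return data.frame of circles (`a`, `b`, `r`, `votes`, `score`, and if
#'   refined `aRefined`, `bRefined`).
#' @export
detectCircles <- function(image, rMin, rMax, rStep = 1, k = 4L,
                          low = 0.1, high = 0.3, sigma = 1.4,
                          minVotes = 8L, nmsRadius = 5L, refine = TRUE) {
    em <- detectEdges(image, low = low, high = high, sigma = sigma)
    acc <- houghCircleAccumulate(em, rMin, rMax, rStep)
    pk <- houghCirclePeaks(acc, k = k, minVotes = minVotes,
                           nmsRadius = nmsRadius)
    if (refine && nrow(pk)) {
        ref <- lapply(seq_len(nrow(pk)), function(i)
            refineCenter(image, pk$a[i], pk$b[i], pk$r[i]))
        pk$aRefined <- vapply(ref, `[[`, numeric(1), "a")
        pk$bRefined <- vapply(ref, `[[`, numeric(1), "b")
        pk$rRefined <- vapply(ref, `[[`, numeric(1), "r")
    }
    pk
}
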