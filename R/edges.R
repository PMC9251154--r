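## Pad a matrix by replicating its border rows/cols k times (symmetric-ish
## extension adequate for small smoothing kernels).
.padReplicate <- function(m, k) {
    m <- m[c(rep(1, k), seq_len(nrow(m)), rep(nrow(m), k)), , drop = FALSE]
    m[, c(rep(1, k), seq_len(ncol(m)), rep(ncol(m), k)), drop = FALSE]
}

## Separable convolution with a 1-D kernel along rows then columns.
.sepConv <- function(m, kern) {
    k <- (length(kern) - 1) / 2
    p <- .padReplicate(m, k)
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(0, nr + 2 * k, nc)
    for (i in seq_along(kern))
        out <- out + kern[i] * p[, i + seq_len(nc) - 1, drop = FALSE]
    res <- matrix(0, nr, nc)
    for (i in seq_along(kern))
        res <- res + kern[i] * out[i + seq_len(nr) - 1, , drop = FALSE]
    res
}

.gaussKernel <- function(sigma) {
    k <- max(1L, ceiling(3 * sigma))
    x <- (-k):k
    w <- exp(-x^2 / (2 * sigma^2))
    w / sum(w)
}

## Shift a matrix by (dr, dc), zero-filling the vacated border.
.shift <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(0, nr, nc)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    okR <- rs >= 1 & rs <= nr; okC <- cs >= 1 & cs <= nc
    out[okR, okC] <- m[rs[okR], cs[okC]]
    out
}

#' Canny-style edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and hysteresis thresholding: pixels above
#' `high` seed edges which grow through 8-connected pixels above `low`.
#' Thresholds are relative to the maximum gradient magnitude, so they are
#' invariant to intensity scaling.
#'
#' @param image an [ImageSlice-class] or numeric matrix.
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude; `0 <= low < high`.
#' @param sigma Gaussian pre-smoothing sd in px (default 1.4).
#' @return an [EdgeMap-class]; its `gradient` slot holds the (unsuppressed)
#'   gradient magnitudes.
#' @export
detectEdges <- function(image, low = 0.1, high = 0.3, sigma = 1.4) {
    if (is(image, "ImageSlice")) image <- image@intensity
    .stopIf(!(low >= 0 && low < high), "need 0 <= low < high")
    sm <- if (sigma > 0) .sepConv(image, .gaussKernel(sigma)) else image
    ## Sobel
    p <- .padReplicate(sm, 1)
    nr <- nrow(sm); nc <- ncol(sm)
    ri <- 1 + seq_len(nr); ci <- 1 + seq_len(nc)
    gr <- (p[ri + 1, ci - 1] + 2 * p[ri + 1, ci] + p[ri + 1, ci + 1] -
           p[ri - 1, ci - 1] - 2 * p[ri - 1, ci] - p[ri - 1, ci + 1]) / 8
    gc <- (p[ri - 1, ci + 1] + 2 * p[ri, ci + 1] + p[ri + 1, ci + 1] -
           p[ri - 1, ci - 1] - 2 * p[ri, ci - 1] - p[ri + 1, ci - 1]) / 8
    mag <- sqrt(gr^2 + gc^2)
    mx <- max(mag)
    if (mx == 0)
        return(new("EdgeMap", edges = matrix(FALSE, nr, nc), gradient = mag))
    ## non-maximum suppression: compare against neighbours along the
    ## gradient direction quantized to 0/45/90/135 degrees
    ang <- atan2(gc, gr) %% pi
    sector <- (floor(ang / (pi / 4) + 0.5)) %% 4  # 0:r, 1:diag, 2:c, 3:anti
    offs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
    keep <- matrix(FALSE, nr, nc)
    for (s in 0:3) {
        o <- offs[[s + 1]]
        nb1 <- .shift(mag, o[1], o[2])
        nb2 <- .shift(mag, -o[1], -o[2])
        keep <- keep | (sector == s & mag >= nb1 & mag >= nb2)
    }
    strong <- keep & (mag >= high * mx)
    weak <- keep & (mag >= low * mx)
    ## hysteresis by iterated dilation of strong within weak
    repeat {
        grown <- strong
        for (dr in -1:1) for (dc in -1:1)
            if (dr || dc) grown <- grown | .shift(strong, dr, dc)
        grown <- grown & weak
        if (identical(grown, strong)) break
        strong <- grown
    }
    new("EdgeMap", edges = strong, gradient = mag)
}
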