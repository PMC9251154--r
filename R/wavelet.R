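## Orthogonal Daubechies filters (scaling/low-pass coefficients).
## "db4" follows the usual naming by vanishing moments (8 taps).
.waveletFilters <- list(
    haar = c(1, 1) / sqrt(2),
    db2  = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4  = c(0.230377813308855230, 0.714846570552541530,
             0.630880767929590360, -0.027983769416983850,
             -0.187034811718881140, 0.030841381835986965,
             0.032883011666982945, -0.010597401784997278)
)

## Quadrature-mirror high-pass from the low-pass: g[k] = (-1)^k h[L-1-k].
.qmf <- function(h) (-1)^(seq_along(h) - 1) * rev(h)

## One periodized analysis step along a vector of even length N:
## a[k] = sum_n h[n] x[(2k + n) mod N] (0-based), likewise d with g.
.dwtStep <- function(x, h, g) {
    N <- length(x)
    L <- length(h)
    k <- 2 * (seq_len(N / 2) - 1)
    idx <- (outer(k, seq_len(L) - 1, `+`) %% N) + 1
    xm <- matrix(x[idx], nrow = N / 2)
    list(a = drop(xm %*% h), d = drop(xm %*% g))
}

## Adjoint (= inverse, the transform is orthogonal) of .dwtStep.
.idwtStep <- function(a, d, h, g) {
    N <- 2 * length(a)
    L <- length(h)
    x <- numeric(N)
    for (k in seq_along(a)) {
        idx <- ((2 * (k - 1) + seq_len(L) - 1) %% N) + 1
        x[idx] <- x[idx] + h * a[k] + g * d[k]
    }
    x
}

.dwt2Level <- function(m, h, g) {
    ## transform rows, then columns; [A|D] packing keeps everything in one
    ## matrix with LL in the top-left quadrant
    rowT <- t(vapply(seq_len(nrow(m)), function(i) {
        s <- .dwtStep(m[i, ], h, g)
        c(s$a, s$d)
    }, numeric(ncol(m))))
    out <- vapply(seq_len(ncol(rowT)), function(j) {
        s <- .dwtStep(rowT[, j], h, g)
        c(s$a, s$d)
    }, numeric(nrow(m)))
    out
}

.idwt2Level <- function(m, h, g) {
    nr <- nrow(m); nc <- ncol(m)
    colT <- vapply(seq_len(nc), function(j)
        .idwtStep(m[seq_len(nr / 2), j], m[nr / 2 + seq_len(nr / 2), j], h, g),
        numeric(nr))
    t(vapply(seq_len(nr), function(i)
        .idwtStep(colT[i, seq_len(nc / 2)], colT[i, nc / 2 + seq_len(nc / 2)], h, g),
        numeric(nc)))
}

#' Wavelet denoising parameters
#'
#' @param family `"haar"`, `"db2"` or `"db4"` (Daubechies, named by
#'   vanishing moments). Default `"db4"`.
#' @param levels decomposition depth; both image dimensions must be
#'   divisible by `2^levels` (the transform is periodized).
#' @param thresholdRule `"soft"` (shrinkage, default) or `"hard"`.
#' @param thresholdScale multiplier on the universal threshold; 0 disables
#'   thresholding entirely (pure decompose/reconstruct).
#' @return a validated parameter list of class `WaveletParams`.
#' @export
waveletParams <- function(family = c("db4", "db2", "haar"), levels = 3L,
                          thresholdRule = c("soft", "hard"),
                          thresholdScale = 1) {
    family <- match.arg(family)
    thresholdRule <- match.arg(thresholdRule)
    .stopIf(levels < 1, "levels must be >= 1")
    .stopIf(thresholdScale < 0, "thresholdScale must be >= 0")
    structure(list(family = family, levels = as.integer(levels),
                   thresholdRule = thresholdRule,
                   thresholdScale = as.numeric(thresholdScale)),
              class = "WaveletParams")
}

#' 2-D periodized discrete wavelet transform
#'
#' Separable multi-level DWT with an orthonormal Daubechies filter bank and
#' periodic boundary extension, so that [idwt2()] inverts it exactly (to
#' machine precision). Each level repacks the current approximation into
#' `[LL | LH; HL | HH]` quadrants in place, giving the standard pyramid
#' layout in a single matrix.
#'
#' @param m numeric matrix; both dimensions divisible by `2^levels`.
#' @param family,levels see [waveletParams()].
#' @return matrix of coefficients in pyramid layout, plus attributes
#'   `levels` and `family`.
#' @export
dwt2 <- function(m, family = "db4", levels = 3L) {
    h <- .waveletFilters[[family]]
    .stopIf(is.null(h), "unknown wavelet family '%s'", family)
    g <- .qmf(h)
    nr <- nrow(m); nc <- ncol(m)
    .stopIf(nr %% 2^levels != 0 || nc %% 2^levels != 0,
            "image %dx%d is not divisible by 2^levels = %d",
            nr, nc, 2^levels)
    .stopIf(2^levels > min(nr, nc),
            "levels = %d too deep for a %dx%d image", levels, nr, nc)
    out <- m
    for (l in seq_len(levels)) {
        ri <- seq_len(nr / 2^(l - 1)); ci <- seq_len(nc / 2^(l - 1))
        out[ri, ci] <- .dwt2Level(out[ri, ci, drop = FALSE], h, g)
    }
    structure(out, levels = levels, family = family)
}

#' @param w coefficient matrix from [dwt2()].
#' @rdname dwt2
#' @export
idwt2 <- function(w, family = attr(w, "family"),
                  levels = attr(w, "levels")) {
    h <- .waveletFilters[[family]]
    g <- .qmf(h)
    nr <- nrow(w); nc <- ncol(w)
    out <- unclass(w)
    for (l in rev(seq_len(levels))) {
        ri <- seq_len(nr / 2^(l - 1)); ci <- seq_len(nc / 2^(l - 1))
        out[ri, ci] <- .idwt2Level(out[ri, ci, drop = FALSE], h, g)
    }
    attributes(out) <- list(dim = dim(w))
    out
}

#' Denoise an image slice by wavelet coefficient shrinkage
#'
#' Decomposes the slice with a periodized orthonormal DWT, thresholds the
#' detail coefficients, and reconstructs. The threshold is the universal
#' threshold `sigma_hat * sqrt(2 log N)` (N = pixel count) scaled by
#' `thresholdScale`, with the noise level `sigma_hat` estimated from the
#' median absolute deviation of the finest diagonal (HH) subband,
#' `median(|HH|) / 0.6745`. With `thresholdScale = 0` the function reduces
#' to decompose + reconstruct and returns the input to machine precision.
#'
#' @param image an [ImageSlice-class] (or plain matrix).
#' @param params a [waveletParams()] list.
#' @return an `ImageSlice` of the same shape and spacing.
#' @seealso [snr()] to quantify the improvement against a reference.
#' @export
denoiseWavelet <- function(image, params = waveletParams()) {
    sp <- c(1, 1)
    if (is(image, "ImageSlice")) {
        sp <- image@spacing
        image <- image@intensity
    }
    .stopIf(any(!is.finite(image)), "image must be finite-valued")
    w <- dwt2(image, params$family, params$levels)
    if (params$thresholdScale > 0) {
        nr <- nrow(w); nc <- ncol(w)
        hh <- w[nr / 2 + seq_len(nr / 2), nc / 2 + seq_len(nc / 2)]
        sigmaHat <- stats::median(abs(hh)) / 0.6745
        thr <- params$thresholdScale * sigmaHat * sqrt(2 * log(length(image)))
        detail <- matrix(TRUE, nr, nc)
        la <- params$levels
        detail[seq_len(nr / 2^la), seq_len(nc / 2^la)] <- FALSE  # keep LL
        d <- w[detail]
        w[detail] <- if (params$thresholdRule == "soft")
            sign(d) * pmax(abs(d) - thr, 0)
        else
            d * (abs(d) > thr)
    }
    ImageSlice(idwt2(w, params$family, params$levels), sp)
}

#' Signal-to-noise ratio against a reference image
#'
#' `10 log10(sum(reference^2) / sum((image - reference)^2))` in decibels.
#' A zero residual (image identical to the reference) returns `Inf` as the
#' perfect-reconstruction sentinel.
#'
#' @param image,reference matrices or [ImageSlice-class]s of equal shape.
#' @return SNR in dB (possibly `Inf`).
#' @export
snr <- function(image, reference) {
    if (is(image, "ImageSlice")) image <- image@intensity
    if (is(reference, "ImageSlice")) reference <- reference@intensity
    .stopIf(!identical(dim(image), dim(reference)),
            "image (%s) and reference (%s) shapes differ",
            paste(dim(image), collapse = "x"),
            paste(dim(reference), collapse = "x"))
    resid <- sum((image - reference)^2)
    if (resid == 0) return(Inf)
    10 * log10(sum(reference^2) / resid)
}
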