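## Independent brute-force oracles, deliberately written as plain loops so
## they share no code path with the package's vectorized implementations.

## Line Hough oracle: one vote per (edge pixel, theta bin) at the rho bin
## nearest a*cos(theta) + b*sin(theta).
bruteLineAccumulator <- function(E, nTheta = 180L, rhoRes = 1) {
    nr <- nrow(E); nc <- ncol(E)
    theta <- (seq_len(nTheta) - 1) * pi / nTheta
    D <- ceiling(sqrt(nr^2 + nc^2) / rhoRes) * rhoRes
    rho <- seq(-D, D, by = rhoRes)
    acc <- matrix(0L, nTheta, length(rho))
    for (a in seq_len(nr)) for (b in seq_len(nc)) {
        if (!E[a, b]) next
        for (i in seq_len(nTheta)) {
            r <- a * cos(theta[i]) + b * sin(theta[i])
            j <- round((r + D) / rhoRes) + 1
            acc[i, j] <- acc[i, j] + 1L
        }
    }
    list(votes = acc, theta = theta, rho = rho)
}

## First-octant midpoint circle points, reflected: the closed-form
## definition of the rasterized centre locus.
bruteCircleLocus <- function(r) {
    pts <- NULL
    for (da in 0:floor(r / sqrt(2))) {
        db <- round(sqrt(r^2 - da^2))
        for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
            pts <- rbind(pts, c(s1 * da, s2 * db), c(s1 * db, s2 * da))
        }
    }
    unique(pts)
}

## Circle Hough oracle: triple loop edge pixels x radii x locus offsets.
bruteCircleAccumulator <- function(E, rMin, rMax, rStep = 1) {
    nr <- nrow(E); nc <- ncol(E)
    rBins <- seq(rMin, rMax, by = rStep)
    acc <- array(0L, dim = c(nr, nc, length(rBins)))
    for (a in seq_len(nr)) for (b in seq_len(nc)) {
        if (!E[a, b]) next
        for (k in seq_along(rBins)) {
            loc <- bruteCircleLocus(rBins[k])
            for (m in seq_len(nrow(loc))) {
                ca <- a + loc[m, 1]; cb <- b + loc[m, 2]
                if (ca >= 1 && ca <= nr && cb >= 1 && cb <= nc)
                    acc[ca, cb, k] <- acc[ca, cb, k] + 1L
            }
        }
    }
    acc
}

## Pearson chi-square by direct summation.
bruteChiSquare <- function(counts) {
    rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
    stat <- 0
    for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
        e <- rs[i] * cs[j] / n
        stat <- stat + (counts[i, j] - e)^2 / e
    }
    stat
}

## Paired t by the textbook formula t = dbar / (sd / sqrt(n)).
brutePairedT <- function(pre, post) {
    d <- pre - post
    n <- length(d)
    dbar <- sum(d) / n
    s <- sqrt(sum((d - dbar)^2) / (n - 1))
    t <- dbar / (s / sqrt(n))
    list(t = t, df = n - 1,
         p = 2 * stats::pt(-abs(t), n - 1))
}

## 1-D periodized analysis matrix for a wavelet filter: rows 1..N/2 the
## low-pass at even shifts, rows N/2+1..N the high-pass. Used to check the
## package's pyramid DWT against an explicit orthogonal matrix.
dwtMatrix <- function(N, h) {
    L <- length(h)
    g <- (-1)^(seq_len(L) - 1) * rev(h)
    T <- matrix(0, N, N)
    for (k in seq_len(N / 2)) {
        for (n in seq_len(L)) {
            j <- ((2 * (k - 1) + n - 1) %% N) + 1
            T[k, j] <- T[k, j] + h[n]
            T[N / 2 + k, j] <- T[N / 2 + k, j] + g[n]
        }
    }
    T
}

## Exhaustive collinear-triple oracle: TLS residual of each triple.
tlsResidual <- function(pts) {
    ctr <- colMeans(pts)
    X <- sweep(pts, 2, ctr)
    s <- svd(X)
    nrm <- c(-s$v[2, 1], s$v[1, 1])
    max(abs(X %*% nrm))
}

## Random rotation matrices for invariance tests.
randomRotation2 <- function() {
    th <- stats::runif(1, 0, 2 * pi)
    matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
}
randomRotation3 <- function() {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
             2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
             2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
           3)
}

## An 8-point frame template (mm) used across matching/registration tests:
## anchors A-B are the unique longest pair; M1..M4 sit on one rod
## (collinear with A).
testTemplate <- function() {
    frameTemplate(
        data.frame(label = c("A", "B", "M1", "M2", "M3", "C", "D", "E"),
                   x = c(0, 100, 20, 30, 40, 70, 50, 80),
                   y = c(0, 0, 30, 45, 60, 40, 80, 25),
                   z = 0),
        anchors = c("A", "B"),
        collinearGroups = list(c("A", "M1", "M2", "M3")))
}
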