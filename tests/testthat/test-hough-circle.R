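test_that("one edge pixel votes on the centre locus circle (Fig-2 duality)", {
    E <- matrix(FALSE, 40, 40)
    E[20, 22] <- TRUE
    acc <- houghCircleAccumulate(E, rMin = 7, rMax = 7)
    hit <- which(votes(acc)[, , 1] > 0, arr.ind = TRUE)
    off <- circleOffsets(7)
    expected <- cbind(20 + off[, "da"], 22 + off[, "db"])
    expected <- expected[expected[, 1] >= 1 & expected[, 1] <= 40 &
                         expected[, 2] >= 1 & expected[, 2] <= 40, ]
    expect_setequal(paste(hit[, 1], hit[, 2]),
                    paste(expected[, 1], expected[, 2]))
    expect_true(all(votes(acc) %in% 0:1))
})

test_that("an ideal circle's votes peak exactly at (a, b, r)", {
    E <- matrix(FALSE, 64, 64)
    off <- circleOffsets(10)
    E[cbind(30 + off[, 1], 40 + off[, 2])] <- TRUE
    acc <- houghCircleAccumulate(E, rMin = 5, rMax = 15)
    mx <- which(votes(acc) == max(votes(acc)), arr.ind = TRUE)
    expect_equal(unname(mx[1, ]), c(30L, 40L, 6L))   # r bin 6 <-> radius 10
    expect_equal(acc@rBins[mx[1, 3]], 10)
    ## the peak collects one vote from every locus pixel
    expect_equal(max(votes(acc)), nrow(off))
})

test_that("total votes equal the enumerated in-bounds locus bins", {
    set.seed(5)
    E <- matrix(runif(32 * 32) < 0.02, 32, 32)
    rBins <- seq(4, 10, by = 2)
    acc <- houghCircleAccumulate(E, 4, 10, 2)
    expected <- 0L
    for (p in which(E)) {
        a <- (p - 1) %% 32 + 1; b <- (p - 1) %/% 32 + 1
        for (r in rBins) {
            loc <- circleOffsets(r)
            ca <- a + loc[, 1]; cb <- b + loc[, 2]
            expected <- expected + sum(ca >= 1 & ca <= 32 & cb >= 1 & cb <= 32)
        }
    }
    expect_equal(sum(votes(acc)), expected)
})

test_that("circle accumulator equals the brute-force triple loop exactly", {
    set.seed(31)
    E <- matrix(runif(48 * 48) < 0.008, 48, 48)
    acc <- houghCircleAccumulate(E, 3, 9, 1)
    expect_identical(unname(votes(acc)), bruteCircleAccumulator(E, 3, 9, 1))
})

test_that("two rendered circles are both recovered to sub-pixel accuracy", {
    spec <- phantomSpec(circles = data.frame(a = c(35.4, 85.2), b = c(40.7, 88.6),
                                             r = c(9, 15)),
                        noiseSigma = 0)
    sl <- makePhantomSlice(spec)
    pk <- detectCircles(sl$image, 5, 20, k = 2)
    expect_equal(nrow(pk), 2L)
    pk <- pk[order(pk$a), ]
    expect_lt(abs(pk$aRefined[1] - 35.4), 1)
    expect_lt(abs(pk$bRefined[1] - 40.7), 1)
    expect_lt(abs(pk$rRefined[1] - 9), 1)
    expect_lt(abs(pk$aRefined[2] - 85.2), 1)
    expect_lt(abs(pk$bRefined[2] - 88.6), 1)
    expect_lt(abs(pk$rRefined[2] - 15), 1)
})

test_that("normalized peaks prefer the better-supported circle; empty in, empty out", {
    ## full circle vs half arc of the same radius: the full one wins k = 1
    E <- matrix(FALSE, 80, 80)
    off <- circleOffsets(9)
    E[cbind(25 + off[, 1], 25 + off[, 2])] <- TRUE
    half <- off[off[, 1] >= 0, ]
    E[cbind(55 + half[, 1], 55 + half[, 2])] <- TRUE
    acc <- houghCircleAccumulate(E, 6, 12)
    pk <- houghCirclePeaks(acc, k = 1)
    expect_equal(c(pk$a, pk$b, pk$r), c(25, 25, 9))
    expect_equal(pk$votes, nrow(off))

    empty <- houghCircleAccumulate(matrix(FALSE, 20, 20), 3, 6)
    expect_equal(nrow(houghCirclePeaks(empty, k = 3)), 0L)
    expect_error(houghCircleAccumulate(matrix(FALSE, 20, 20), -1, 5), "rMin")
})

test_that("peak extraction is deterministic under vote ties", {
    E <- matrix(FALSE, 50, 50)
    for (ctr in list(c(15, 15), c(15, 35), c(35, 15), c(35, 35))) {
        off <- circleOffsets(6)
        E[cbind(ctr[1] + off[, 1], ctr[2] + off[, 2])] <- TRUE
    }
    acc <- houghCircleAccumulate(E, 4, 8)
    p1 <- houghCirclePeaks(acc, k = 4)
    p2 <- houghCirclePeaks(acc, k = 4)
    expect_identical(p1, p2)
    ## four identical-score peaks: ordered lexicographically by (a, b)
    expect_equal(p1$a, c(15, 15, 35, 35))
    expect_equal(p1$b, c(15, 35, 15, 35))
})

test_that("sub-pixel refinement converges on fractional truth", {
    spec <- phantomSpec(circles = data.frame(a = 30.4, b = 40.7, r = 10),
                        noiseSigma = 0)
    img <- makePhantomSlice(spec)$image
    rc <- refineCenter(img, 30, 41, 10)
    expect_lt(abs(rc$a - 30.4), 0.1)
    expect_lt(abs(rc$b - 40.7), 0.1)

    ## already-exact centre is a fixed point
    spec2 <- phantomSpec(circles = data.frame(a = 30, b = 41, r = 10),
                         noiseSigma = 0)
    rc2 <- refineCenter(makePhantomSlice(spec2)$image, 30, 41, 10)
    expect_lt(abs(rc2$a - 30), 0.1)
    expect_lt(abs(rc2$b - 41), 0.1)

    ## near-border window is flagged as clipped
    spec3 <- phantomSpec(width = 40, height = 40,
                         circles = data.frame(a = 8, b = 8, r = 6),
                         noiseSigma = 0)
    expect_true(refineCenter(makePhantomSlice(spec3)$image, 8, 8, 6)$clipped)
    expect_error(refineCenter(matrix(0, 20, 20), 30, 10, 5), "outside")
})

test_that("refinement beats the coarse Hough centre under noise", {
    coarseErr <- refinedErr <- numeric(0)
    for (s in 1:20) {
        set.seed(s + 400)
        a <- runif(1, 45, 85); b <- runif(1, 45, 85)
        spec <- phantomSpec(circles = data.frame(a = a, b = b, r = 12),
                            noiseSigma = 10, seed = s)
        pk <- detectCircles(makePhantomSlice(spec)$image, 8, 16, k = 1)
        coarseErr <- c(coarseErr, sqrt((pk$a - a)^2 + (pk$b - b)^2))
        refinedErr <- c(refinedErr, sqrt((pk$aRefined - a)^2 +
                                         (pk$bRefined - b)^2))
    }
    expect_lt(mean(refinedErr), mean(coarseErr))
    expect_lt(mean(refinedErr), 0.5)
})
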