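test_that("noiseless renders match their analytic construction", {
    spec <- phantomSpec(circles = data.frame(a = 30, b = 40, r = 10,
                                             amplitude = 150, thickness = 3),
                        background = 20, noiseSigma = 0)
    img <- intensity(makePhantomSlice(spec)$image)
    ## a pixel exactly on the annulus carries the full feature amplitude
    expect_gte(img[30, 50], 20 + 0.5 * 150)
    expect_equal(img[30, 50], 20 + 150)
    ## far from the annulus the image is pure background
    expect_equal(img[100, 100], 20)

    empty <- phantomSpec(background = 20, noiseSigma = 0)
    expect_true(all(intensity(makePhantomSlice(empty)$image) == 20))
})

test_that("phantom generation is deterministic per (spec, seed)", {
    spec <- phantomSpec(circles = data.frame(a = 50, b = 60, r = 12),
                        lines = data.frame(theta = 0.7, rho = 40),
                        noiseSigma = 15, seed = 42L)
    s1 <- makePhantomSlice(spec)
    s2 <- makePhantomSlice(spec)
    expect_identical(intensity(s1$image), intensity(s2$image))

    specB <- phantomSpec(circles = data.frame(a = 50, b = 60, r = 12),
                         noiseSigma = 15, seed = 43L)
    expect_false(identical(intensity(makePhantomSlice(specB)$image),
                           intensity(s1$image)))
})

test_that("truth records every feature and rejects out-of-bounds specs", {
    spec <- phantomSpec(circles = data.frame(a = c(30.4, 80.1), b = c(40.7, 90.9),
                                             r = c(8, 11)),
                        lines = data.frame(theta = c(0, 1.1), rho = c(25, 60)),
                        noiseSigma = 0)
    tr <- makePhantomSlice(spec)$truth
    expect_equal(trueCircles(tr)$a, c(30.4, 80.1))
    expect_equal(trueLines(tr)$rho, c(25, 60))

    expect_error(phantomSpec(circles = data.frame(a = 5, b = 5, r = 10)),
                 "bounds")
    expect_error(phantomSpec(circles = data.frame(a = 50, b = 50, r = 1)),
                 "r >= 2|radii")
    expect_error(phantomSpec(noiseSigma = -1), "noiseSigma")
})

test_that("noiseless features are recoverable by template correlation within 0.5 px", {
    ## truth fidelity: cross-correlate the render with a shifted copy of the
    ## feature and check the best integer shift is the origin
    spec <- phantomSpec(circles = data.frame(a = 60.3, b = 52.6, r = 12),
                        noiseSigma = 0)
    img <- intensity(makePhantomSlice(spec)$image) - 20
    score <- function(da, db) {
        tpl <- intensity(makePhantomSlice(
            phantomSpec(circles = data.frame(a = 60.3 + da, b = 52.6 + db,
                                             r = 12),
                        noiseSigma = 0))$image) - 20
        sum(img * tpl)
    }
    s0 <- score(0, 0)
    for (da in c(-1, -0.5, 0.5, 1)) {
        expect_lt(score(da, 0), s0)
        expect_lt(score(0, da), s0)
    }
})

test_that("volume phantoms record AC/PC truth and per-fiducial frame points", {
    circ <- data.frame(a = c(20, 20, 100, 100, 60, 20, 100, 60),
                       b = c(20, 100, 20, 100, 20, 60, 60, 100),
                       r = 6)
    spec <- phantomSpec(circles = circ, noiseSigma = 0)
    ph <- makePhantomVolume(spec, nSlices = 6,
                            ac = c(0, 10, 0), pc = c(0, -15, 0))
    expect_equal(dim(ph$image), c(128L, 128L, 6L))
    expect_equal((ph$truth@ac + ph$truth@pc) / 2, c(0, -2.5, 0))
    expect_equal(nrow(framePoints(ph$truth)), 8L)

    ph2 <- makePhantomVolume(spec, nSlices = 6,
                             ac = c(0, 10, 0), pc = c(0, -15, 0))
    expect_identical(intensity(ph$image), intensity(ph2$image))

    expect_error(makePhantomVolume(spec, nSlices = 2), "3 slices")
})

test_that("outcome cohorts hit requested category counts exactly", {
    coh <- makeOutcomeCohort(40, 40, c(37, 1, 2), c(35, 2, 3), seed = 11)
    expect_equal(nrow(coh), 80L)
    expect_true(all(coh$updrsPre > 0))
    tab <- counts(tabulateOutcomes(coh))
    expect_equal(unname(tab["observation", ]), c(37L, 1L, 2L))
    expect_equal(unname(tab["control", ]), c(35L, 2L, 3L))

    ## all-markedly cohort: every rate above the markedly-effective cut
    coh2 <- makeOutcomeCohort(10, 10, c(10, 0, 0), c(10, 0, 0), seed = 2)
    expect_true(all(improvementRate(coh2$updrsPre, coh2$updrsPost) >= 50))

    expect_identical(makeOutcomeCohort(40, 40, c(37, 1, 2), c(35, 2, 3), seed = 11),
                     coh)
    expect_error(makeOutcomeCohort(40, 40, c(37, 1, 3), c(35, 2, 3), seed = 1),
                 "sum")
})

test_that("cohort category round-trip holds across random count vectors", {
    set.seed(99)
    for (i in 1:8) {
        n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
        c1 <- as.vector(stats::rmultinom(1, n1, c(0.6, 0.2, 0.2)))
        c2 <- as.vector(stats::rmultinom(1, n2, c(0.5, 0.25, 0.25)))
        coh <- makeOutcomeCohort(n1, n2, c1, c2, seed = i)
        tab <- counts(tabulateOutcomes(coh))
        expect_equal(unname(tab["observation", ]), c1)
        expect_equal(unname(tab["control", ]), c2)
    }
})
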