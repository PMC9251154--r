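test_that("noiseless rigid motions are recovered to machine precision", {
    set.seed(12)
    tpl3 <- cbind(c(0, 100, 20, 30, 40, 70, 50, 80),
                  c(0, 0, 30, 45, 60, 40, 80, 25),
                  c(0, 5, 40, 10, 25, 35, 15, 30))
    for (s in 1:20) {
        R <- randomRotation3()
        tr <- runif(3, -50, 50)
        moved <- t(R %*% t(tpl3)) + rep(tr, each = nrow(tpl3))
        ft <- fitRigidTransform(tpl3, moved)
        expect_lt(max(abs(rotation(ft) - R)), 1e-9)
        expect_lt(max(abs(translation(ft) - tr)), 1e-9)
        expect_lt(rmsError(ft), 1e-9)
    }
    ## identity correspondence gives the identity transform
    ft0 <- fitRigidTransform(tpl3, tpl3)
    expect_equal(rotation(ft0), diag(3), tolerance = 1e-12)
    expect_equal(translation(ft0), c(0, 0, 0), tolerance = 1e-12)
})

test_that("residuals match a brute-force recomputation and bound the FRE", {
    set.seed(9)
    src <- cbind(runif(8, 0, 100), runif(8, 0, 100))
    dst <- src + matrix(rnorm(16, sd = 0.5), ncol = 2)
    ft <- fitRigidTransform(src, dst)
    manual <- sqrt(rowSums((t(rotation(ft) %*% t(src)) +
                            rep(translation(ft), each = 8) - dst)^2))
    expect_equal(residuals(ft), manual, tolerance = 1e-12)
    expect_equal(rmsError(ft), sqrt(mean(manual^2)), tolerance = 1e-12)
    expect_lte(rmsError(ft), max(manual))
})

test_that("jittered fiducials give an FRE near the expected scale", {
    set.seed(77)
    tpl <- cbind(c(0, 100, 20, 30, 40, 70, 50, 80),
                 c(0, 0, 30, 45, 60, 40, 80, 25))
    fre <- vapply(1:25, function(s) {
        set.seed(s)
        moved <- tpl + matrix(rnorm(16, sd = 0.2), ncol = 2)
        rmsError(fitRigidTransform(tpl, moved))
    }, numeric(1))
    expect_gt(mean(fre), 0.1)
    expect_lt(mean(fre), 0.3)
})

test_that("collinear configurations are rejected as rank-deficient", {
    line <- cbind(1:5, 2 * (1:5))
    expect_error(fitRigidTransform(line, line + 1), "collinear|rank")
    line3 <- cbind(1:5, 2 * (1:5), 3 * (1:5))
    expect_error(fitRigidTransform(line3, line3), "collinear|rank")
    expect_error(fitRigidTransform(cbind(1:2, 1:2), cbind(1:2, 1:2)),
                 "at least 3")
})

test_that("transforms apply, invert and round-trip exactly", {
    set.seed(4)
    R <- randomRotation3()
    ft <- new("FrameTransform", rotation = R, translation = c(1, 2, 3),
              residuals = numeric(), rms = 0)
    expect_equal(applyTransform(ft, c(0, 0, 0)), c(1, 2, 3))
    pts <- matrix(rnorm(30), ncol = 3)
    back <- applyTransform(invertTransform(ft), applyTransform(ft, pts))
    expect_lt(max(abs(back - pts)), 1e-9)

    ident <- fitRigidTransform(pts[1:4, ], pts[1:4, ])
    expect_equal(applyTransform(ident, pts), pts, tolerance = 1e-9)
    expect_error(applyTransform(ft, cbind(1, 2)), "dimension")
})

test_that("the AC-PC frame is built as specified on axis-aligned input", {
    f <- buildAcpc(c(0, 12, 0), c(0, -12, 0), c(0, 0, 10))
    expect_equal(f@origin, c(0, 0, 0))
    expect_equal(acpcCoords(f, c(0, 12, 0)), c(x = 0, y = 12, z = 0))
    expect_equal(acpcCoords(f, c(0, -12, 0)), c(x = 0, y = -12, z = 0))
    expect_equal(unname(f@axes[, 1]), c(1, 0, 0))   # X to the right

    expect_error(buildAcpc(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)), "coincide")
    expect_error(buildAcpc(c(0, 12, 0), c(0, -12, 0), c(0, 3, 0)),
                 "AC-PC line")
})

test_that("AC-PC coordinates are invariant under global rigid motion", {
    set.seed(23)
    ac <- c(3, 40, 12); pc <- c(2, 16, 11); mid <- c(4, 28, 40)
    tgt <- c(15, 25, 5)
    f0 <- buildAcpc(ac, pc, mid)
    ref <- acpcCoords(f0, tgt)
    for (s in 1:10) {
        R <- randomRotation3()
        tr <- runif(3, -30, 30)
        mv <- function(p) as.vector(R %*% p + tr)
        f1 <- buildAcpc(mv(ac), mv(pc), mv(mid))
        expect_equal(acpcCoords(f1, mv(tgt)), ref, tolerance = 1e-9)
    }
})

test_that("target protocol window is enforced with inclusive boundaries", {
    f <- buildAcpc(c(0, 12, 0), c(0, -12, 0), c(0, 0, 10))
    expect_true(withinProtocol(targetCoordinates(f, "left", 11.5, -1.5, -4)))
    expect_true(withinProtocol(targetCoordinates(f, "right", 11.5, -1.5, -4)))
    expect_false(withinProtocol(targetCoordinates(f, "left", 9, -1.5, -4)))
    expect_true(withinProtocol(targetCoordinates(f, "right", 13, -2, -6)))
    expect_true(withinProtocol(targetCoordinates(f, "left", 10, -1, -2)))
    expect_false(withinProtocol(targetCoordinates(f, "left", 11.5, -2.5, -4)))
    expect_false(withinProtocol(targetCoordinates(f, "left", 11.5, -1.5, -1)))
    ## left targets carry negative x; the world point reflects the frame
    tg <- targetCoordinates(f, "left", 11.5, -1.5, -4)
    expect_equal(unname(coords(tg)), c(-11.5, -1.5, -4))
    expect_equal(tg@world, c(-11.5, -1.5, -4))
})

test_that("error reports decompose FLE, FRE and TRE correctly", {
    truth <- new("PhantomTruth",
                 circles = data.frame(a = c(20, 40, 20, 40), b = c(20, 20, 60, 60),
                                      r = 6),
                 lines = data.frame(theta = numeric(), rho = numeric()),
                 ac = numeric(), pc = numeric(),
                 framePoints = data.frame(label = c("A", "B", "C", "D"),
                                          x = c(20, 40, 20, 40),
                                          y = c(20, 20, 60, 60), z = 0))
    exact <- new("FiducialSet",
                 matches = data.frame(label = c("A", "B", "C", "D"),
                                      imageRow = c(20, 40, 20, 40),
                                      imageCol = c(20, 20, 60, 60),
                                      templateX = c(20, 40, 20, 40),
                                      templateY = c(20, 20, 60, 60),
                                      residual = 0),
                 unmatchedDetections = data.frame(),
                 unmatchedLabels = character())
    ft <- fitRigidTransform(exact)
    rep0 <- evaluateErrors(truth, exact, ft,
                           targets = list(ctr = list(image = c(30, 40),
                                                     frame = c(30, 40))))
    expect_equal(unname(rep0@fle), rep(0, 4))
    expect_equal(rep0@fre, 0, tolerance = 1e-12)
    expect_equal(unname(rep0@tre), 0, tolerance = 1e-12)

    ## displacing one mark by 2 px at 1 mm/px costs exactly 2 mm of FLE
    shifted <- exact
    shifted@matches$imageRow[2] <- 42
    rep1 <- evaluateErrors(truth, shifted, ft, spacing = c(1, 1))
    expect_equal(unname(rep1@fle["B"]), 2)

    bad <- exact
    bad@matches$label[1] <- "Z"
    expect_error(evaluateErrors(truth, bad, ft), "absent from truth")
})

test_that("with jittered fiducials the central TRE stays at or below the FLE", {
    tpl <- cbind(c(0, 100, 20, 30, 40, 70, 50, 80),
                 c(0, 0, 30, 45, 60, 40, 80, 25))
    treS <- fleS <- numeric(0)
    for (s in 1:20) {
        set.seed(s + 600)
        det <- tpl + matrix(rnorm(16, sd = 0.4), ncol = 2)
        ft <- fitRigidTransform(det, tpl)
        ctr <- colMeans(tpl)
        treS <- c(treS, sqrt(sum((applyTransform(ft, ctr) - ctr)^2)))
        fleS <- c(fleS, mean(sqrt(rowSums((det - tpl)^2))))
    }
    expect_lte(mean(treS), mean(fleS))
})
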