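test_that("collinearity grouping finds exactly the analytic line", {
    ## 4 points on col = 2*row + 1 plus one clear outlier
    pts <- rbind(c(1, 3), c(2, 5), c(3, 7), c(4, 9), c(1.5, 10))
    g <- groupCollinear(pts, tol = 0.5)
    expect_length(g, 1L)
    expect_equal(g[[1]], 1:4)

    ## equilateral triangle, side 10: no collinear triple
    tri <- rbind(c(0, 0), c(10, 0), c(5, 5 * sqrt(3)))
    expect_length(groupCollinear(tri, tol = 0.5), 0L)

    expect_error(groupCollinear(rbind(c(1, 1), c(1, 1), c(1, 1)), 0.5),
                 "identical")
    expect_error(groupCollinear(rbind(c(1, 1)), 0.5), "at least 2")
})

test_that("collinear groups agree with exhaustive triple testing", {
    set.seed(8)
    for (rep in 1:6) {
        n <- sample(6:12, 1)
        pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
        ## plant one collinear quadruple
        d <- runif(2); d <- d / sqrt(sum(d^2))
        p0 <- runif(2, 10, 40)
        pts[1:4, ] <- rep(p0, each = 4) + outer(c(0, 15, 30, 45), d)
        tol <- 0.75
        g <- groupCollinear(pts, tol = tol)
        inGroup <- function(i, j, k) any(vapply(g, function(gr)
            all(c(i, j, k) %in% gr), logical(1)))
        for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
            triple <- pts[c(i, j, k), ]
            if (tlsResidual(triple) <= tol * 0.5) {
                ## a comfortably collinear triple must be covered by a group
                expect_true(inGroup(i, j, k),
                            label = sprintf("triple %d-%d-%d covered", i, j, k))
            }
        }
        ## and every reported group is genuinely collinear
        for (gr in g)
            expect_lte(tlsResidual(pts[gr, , drop = FALSE]), tol)
    }
})

test_that("marks under a known rigid motion are labelled perfectly", {
    tpl <- testTemplate()
    pts <- as.matrix(tpl@points[c("x", "y")])
    set.seed(3)
    R <- randomRotation2()
    det <- t(R %*% t(pts)) + rep(c(12, -7), each = nrow(pts))
    fs <- matchMarks(det, tpl, tol = 1)
    expect_equal(nrow(matches(fs)), nrow(pts))
    expect_length(unmatchedLabels(fs), 0L)
    expect_equal(nrow(unmatchedDetections(fs)), 0L)
    ## labels map back to their own template coordinates
    m <- matches(fs)
    expect_equal(m$templateX, tpl@points$x[match(m$label, tpl@points$label)])
    expect_true(all(m$residual < 1e-9))
})

test_that("spurious detections fall into the unmatched set", {
    tpl <- testTemplate()
    pts <- as.matrix(tpl@points[c("x", "y")])
    det <- rbind(pts + 3, c(55, 20))   # pure translation + one spurious point
    fs <- matchMarks(det, tpl, tol = 1)
    expect_equal(nrow(matches(fs)), nrow(pts))
    expect_equal(nrow(unmatchedDetections(fs)), 1L)
    expect_equal(unname(unlist(unmatchedDetections(fs))), c(55, 20))
    expect_true(all(matches(fs)$residual < 1e-9))
})

test_that("labelling survives 0.5 px jitter across seeds", {
    tpl <- testTemplate()
    pts <- as.matrix(tpl@points[c("x", "y")])
    for (s in 0:19) {
        set.seed(s)
        R <- randomRotation2()
        det <- t(R %*% t(pts)) + rep(runif(2, -20, 20), each = nrow(pts)) +
            matrix(runif(2 * nrow(pts), -0.5, 0.5), ncol = 2)
        fs <- matchMarks(det, tpl, tol = 2)
        m <- matches(fs)
        expect_equal(nrow(m), nrow(pts))
        expect_equal(m$templateX,
                     tpl@points$x[match(m$label, tpl@points$label)])
    }
})

test_that("matching is invariant to detection order and rigid motion", {
    tpl <- testTemplate()
    pts <- as.matrix(tpl@points[c("x", "y")])
    set.seed(17)
    det <- pts + matrix(runif(2 * nrow(pts), -0.3, 0.3), ncol = 2)
    ref <- matches(matchMarks(det, tpl, tol = 2))
    for (s in 1:5) {
        set.seed(s + 100)
        perm <- sample(nrow(det))
        mP <- matches(matchMarks(det[perm, ], tpl, tol = 2))
        expect_equal(mP[order(mP$label), ], ref[order(ref$label), ],
                     ignore_attr = TRUE)
        R <- randomRotation2()
        tr <- runif(2, -50, 50)
        mR <- matches(matchMarks(t(R %*% t(det)) + rep(tr, each = nrow(det)),
                                 tpl, tol = 2))
        expect_equal(mR$label[order(mR$templateX, mR$templateY)],
                     ref$label[order(ref$templateX, ref$templateY)])
    }
})

test_that("degenerate matching problems raise informative errors", {
    tpl <- testTemplate()
    pts <- as.matrix(tpl@points[c("x", "y")])
    expect_error(matchMarks(pts[1:2, ], tpl), "at least 3")
    ## detections unrelated to the template: no hypothesis fits
    set.seed(2)
    expect_error(matchMarks(cbind(runif(8, 0, 10), runif(8, 0, 10)),
                            tpl, tol = 0.1), "residual")
    ## a template whose anchors are not the longest pair is rejected
    bad <- frameTemplate(tpl@points, anchors = c("A", "M1"))
    expect_error(matchMarks(pts, bad, tol = 1), "maximum-separation")
})
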