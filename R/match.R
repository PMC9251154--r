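#' Construct a stereotactic frame template
#'
#' @param points data.frame with columns `label`, `x`, `y`, `z` (mm). For
#'   slice (2-D) matching only `x` and `y` are used; `z` may be 0.
#' @param anchors character(2): labels of the anchor pair whose separation
#'   is the unique maximum inter-point distance (the reference axis A-B).
#' @param collinearGroups optional list of label vectors expected to be
#'   collinear.
#' @return a [FrameTemplate-class].
#' @export
frameTemplate <- function(points, anchors, collinearGroups = list()) {
    points <- as.data.frame(points)
    if (is.null(points$z)) points$z <- 0
    points$label <- as.character(points$label)
    new("FrameTemplate", points = points[c("label", "x", "y", "z")],
        anchors = as.character(anchors), collinearGroups = collinearGroups)
}

## Perpendicular residuals of points (n x 2) to their total-least-squares
## (PCA) line; returns list(residuals, ok).
.tlsLineResiduals <- function(pts) {
    ctr <- colMeans(pts)
    X <- sweep(pts, 2, ctr)
    s <- svd(X)
    dir <- s$v[, 1]
    nrm <- c(-dir[2], dir[1])
    list(residuals = abs(X %*% nrm), direction = dir, center = ctr)
}

#' Group detected mark points by collinearity
#'
#' Finds all maximal groups of three or more points whose perpendicular
#' residual to the group's total-least-squares line is at most `tol`.
#' Candidate groups are seeded by every point pair and refined once against
#' the TLS fit; a point may belong to several groups. Groups are sorted by
#' size descending, ties by the smallest member index.
#'
#' @param points numeric n x 2 matrix of (row, col) centres, n >= 2.
#' @param tol perpendicular distance tolerance (px).
#' @return list of integer vectors (row indices into `points`), possibly
#'   empty.
#' @export
groupCollinear <- function(points, tol = 0.5) {
    points <- as.matrix(points)
    .stopIf(nrow(points) < 2, "need at least 2 points")
    .stopIf(ncol(points) != 2, "points must be n x 2")
    n <- nrow(points)
    dup <- stats::dist(points)
    .stopIf(all(dup < 1e-12), "all points are identical (degenerate input)")
    groups <- list()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        p <- points[i, ]; q <- points[j, ]
        L <- .euclid(p, q)
        if (L < 1e-12) next
        dir <- (q - p) / L
        nrm <- c(-dir[2], dir[1])
        d <- abs((points[, 1] - p[1]) * nrm[1] + (points[, 2] - p[2]) * nrm[2])
        cand <- which(d <= 2 * tol)
        if (length(cand) < 3) next
        ## refine against the TLS line of the candidate set
        for (rep in 1:2) {
            fit <- .tlsLineResiduals(points[cand, , drop = FALSE])
            ctr <- fit$center; dir <- fit$direction
            nrm <- c(-dir[2], dir[1])
            dAll <- abs((points[, 1] - ctr[1]) * nrm[1] +
                        (points[, 2] - ctr[2]) * nrm[2])
            newCand <- which(dAll <= tol)
            if (identical(newCand, cand)) break
            cand <- newCand
            if (length(cand) < 3) break
        }
        if (length(cand) < 3) next
        ## verify the final set really satisfies the residual bound
        fit <- .tlsLineResiduals(points[cand, , drop = FALSE])
        if (max(fit$residuals) > tol) next
        groups[[length(groups) + 1]] <- sort(cand)
    }
    if (!length(groups)) return(list())
    groups <- unique(groups)
    ## maximality: drop groups that are strict subsets of another
    keep <- vapply(seq_along(groups), function(i)
        !any(vapply(seq_along(groups), function(j)
            i != j && length(groups[[i]]) < length(groups[[j]]) &&
                all(groups[[i]] %in% groups[[j]]), logical(1))),
        logical(1))
    groups <- groups[keep]
    sz <- vapply(groups, length, integer(1))
    first <- vapply(groups, min, integer(1))
    groups[order(-sz, first)]
}

## 2-D similarity transform mapping (s1, s2) onto (t1, t2), complex form.
.similarityFrom2 <- function(s1, s2, t1, t2) {
    zs <- complex(real = c(s1[1], s2[1]), imaginary = c(s1[2], s2[2]))
    zt <- complex(real = c(t1[1], t2[1]), imaginary = c(t1[2], t2[2]))
    m <- (zt[2] - zt[1]) / (zs[2] - zs[1])
    b <- zt[1] - m * zs[1]
    function(p) {
        z <- m * complex(real = p[, 1], imaginary = p[, 2]) + b
        cbind(Re(z), Im(z))
    }
}

## Greedy one-to-one assignment by ascending distance; ties broken by
## template index then detection coordinates, so the result is independent
## of detection input order.
.greedyAssign <- function(D, detPts) {
    nt <- nrow(D); nd <- ncol(D)
    ord <- order(as.vector(D),
                 rep(seq_len(nt), nd),
                 rep(detPts[, 1], each = nt),
                 rep(detPts[, 2], each = nt))
    tUsed <- logical(nt); dUsed <- logical(nd)
    assign <- rep(NA_integer_, nt)
    for (idx in ord) {
        ti <- (idx - 1) %% nt + 1
        di <- (idx - 1) %/% nt + 1
        if (tUsed[ti] || dUsed[di]) next
        assign[ti] <- di
        tUsed[ti] <- TRUE; dUsed[di] <- TRUE
        if (all(tUsed) || all(dUsed)) break
    }
    assign
}

#' Match detected mark points to frame template labels
#'
#' Implements the anchor-then-order matching flow: the template's anchor
#' pair A-B (its unique maximum inter-point separation) is identified among
#' the detections by exhaustively trying every ordered detection pair as
#' (A, B), aligning the template onto the detections with the similarity
#' transform defined by that pair, assigning the remaining labels to their
#' nearest detections (one-to-one, deterministic tie-breaks), and keeping
#' the hypothesis with the smallest mean residual. Matches whose residual
#' exceeds `tol` are dropped to the unmatched lists.
#'
#' Residuals (and `tol`) are measured in template units (mm): detections
#' are pulled back through the inverse alignment before comparison, so the
#' unknown image scale does not enter.
#'
#' @param detections numeric n x 2 matrix of detected centres
#'   (row, col; px or mm), n >= 3.
#' @param template a [FrameTemplate-class].
#' @param tol match residual tolerance in template units (mm).
#' @return a [FiducialSet-class].
#' @export
matchMarks <- function(detections, template, tol = 2) {
    stopifnot(is(template, "FrameTemplate"))
    det <- as.matrix(detections)
    .stopIf(nrow(det) < 3, "need at least 3 detections (got %d)", nrow(det))
    tp <- template@points
    tpts <- as.matrix(tp[c("x", "y")])
    labels <- tp$label
    ai <- match(template@anchors, labels)
    ## the anchor pair must be recognisable: unique max separation
    Dt <- as.matrix(stats::dist(tpts))
    anchorSep <- Dt[ai[1], ai[2]]
    .stopIf(anchorSep < max(Dt) - 1e-9,
            "anchor pair is not the maximum-separation template pair")
    nMax <- sum(abs(Dt[upper.tri(Dt)] - anchorSep) <= tol)
    .stopIf(nMax > 1,
            "anchor pair ambiguous: %d template pairs share the maximum separation within tol",
            nMax)
    nd <- nrow(det)
    best <- NULL
    bestCost <- Inf
    secondCost <- Inf
    bestPair <- NULL
    for (p in seq_len(nd)) for (q in seq_len(nd)) {
        if (p == q) next
        if (.euclid(det[p, ], det[q, ]) < 1e-9) next
        ## invert: map detections into template space using (p, q) as (A, B)
        toTemplate <- .similarityFrom2(det[p, ], det[q, ],
                                       tpts[ai[1], ], tpts[ai[2], ])
        detT <- toTemplate(det)
        D <- sqrt(outer(tpts[, 1], detT[, 1], `-`)^2 +
                  outer(tpts[, 2], detT[, 2], `-`)^2)
        assign <- .greedyAssign(D, detT)
        resid <- D[cbind(seq_along(assign), assign)]
        cost <- mean(resid, na.rm = TRUE)
        if (cost < bestCost - 1e-12) {
            if (!is.null(bestPair)) secondCost <- bestCost
            bestCost <- cost
            bestPair <- c(p, q)
            best <- list(assign = assign, resid = resid, detT = detT)
        } else if (cost < secondCost) {
            secondCost <- cost
        }
    }
    .stopIf(is.null(best) || !is.finite(bestCost),
            "matching failed: no anchor hypothesis could be evaluated")
    .stopIf(bestCost > tol,
            "matching failed: best mean residual %.3g exceeds tol %.3g",
            bestCost, tol)
    .stopIf(secondCost <= tol && secondCost - bestCost <= 1e-9,
            "matching ambiguous: two anchor hypotheses tie at residual %.3g",
            bestCost)
    ok <- !is.na(best$assign) & best$resid <= tol
    mi <- which(ok)
    matchesDf <- data.frame(label = labels[mi],
                            imageRow = det[best$assign[mi], 1],
                            imageCol = det[best$assign[mi], 2],
                            templateX = tpts[mi, 1],
                            templateY = tpts[mi, 2],
                            residual = best$resid[mi],
                            stringsAsFactors = FALSE)
    usedDet <- best$assign[mi]
    um <- setdiff(seq_len(nd), usedDet)
    new("FiducialSet",
        matches = matchesDf,
        unmatchedDetections = data.frame(imageRow = det[um, 1],
                                         imageCol = det[um, 2]),
        unmatchedLabels = labels[!ok])
}
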