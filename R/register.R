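#' Fit a rigid transform between matched point sets
#'
#' Least-squares rigid (rotation + translation, no scaling) registration by
#' SVD-based orthogonal Procrustes: minimizes `sum ||R p_i + t - q_i||^2`
#' over rotations R (det + 1 enforced, so reflections are never returned)
#' and translations t. A stereotactic frame is rigid, so scaling is
#' deliberately excluded and residuals stay interpretable in mm.
#'
#' @param src numeric n x d matrix of source points (d = 2 or 3), or a
#'   [FiducialSet-class] whose image points (converted to mm by the caller)
#'   are registered onto its template points.
#' @param dst numeric n x d matrix of destination points; ignored when
#'   `src` is a `FiducialSet`.
#' @return a [FrameTransform-class] with per-point residuals and the RMS
#'   residual (the fiducial registration error, FRE).
#' @export
#' @examples
#' tpl <- cbind(c(0, 0, 10, 10), c(0, 10, 0, 10))
#' th <- pi / 7
#' R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
#' ft <- fitRigidTransform(tpl, t(R %*% t(tpl)) + 5)
#' rmsError(ft)
fitRigidTransform <- function(src, dst = NULL) {
    if (is(src, "FiducialSet")) {
        m <- src@matches
        .stopIf(nrow(m) < 3, "need at least 3 matches")
        dst <- as.matrix(m[c("templateX", "templateY")])
        src <- as.matrix(m[c("imageRow", "imageCol")])
    }
    src <- as.matrix(src); dst <- as.matrix(dst)
    d <- ncol(src)
    .stopIf(!d %in% 2:3, "points must be 2-D or 3-D")
    .stopIf(!identical(dim(src), dim(dst)),
            "source and destination point sets must have the same shape")
    n <- nrow(src)
    .stopIf(n < 3, "need at least 3 point pairs (got %d)", n)
    cs <- colMeans(src); cd <- colMeans(dst)
    X <- sweep(src, 2, cs); Y <- sweep(dst, 2, cd)
    sv <- svd(X)
    rank <- sum(sv$d > max(sv$d) * 1e-9)
    .stopIf(rank < 2,
            "degenerate point configuration: centred rank %d (points are collinear)",
            rank)
    H <- crossprod(X, Y)          # d x d cross-covariance
    s <- svd(H)
    S <- diag(d)
    S[d, d] <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% S %*% t(s$u)
    t <- cd - as.vector(R %*% cs)
    fitted <- t(R %*% t(src)) + matrix(t, n, d, byrow = TRUE)
    res <- sqrt(rowSums((fitted - dst)^2))
    new("FrameTransform", rotation = R, translation = t,
        residuals = res, rms = sqrt(mean(res^2)))
}

#' Apply or invert a rigid transform
#'
#' `applyTransform` maps points by `R p + t`; `invertTransform` returns the
#' inverse transform (`R' = R^T`, `t' = -R^T t`), so that applying a
#' transform and then its inverse is the identity to machine precision.
#'
#' @param transform a [FrameTransform-class].
#' @param points numeric n x d matrix (or length-d vector).
#' @return transformed points (same shape as input) / the inverse
#'   `FrameTransform`.
#' @export
applyTransform <- function(transform, points) {
    stopifnot(is(transform, "FrameTransform"))
    vec <- is.null(dim(points))
    p <- if (vec) matrix(points, 1) else as.matrix(points)
    .stopIf(ncol(p) != nrow(transform@rotation),
            "point dimension %d does not match the %d-D transform",
            ncol(p), nrow(transform@rotation))
    out <- t(transform@rotation %*% t(p)) +
        matrix(transform@translation, nrow(p), ncol(p), byrow = TRUE)
    if (vec) drop(out) else out
}

#' @rdname applyTransform
#' @export
invertTransform <- function(transform) {
    stopifnot(is(transform, "FrameTransform"))
    R <- t(transform@rotation)
    new("FrameTransform", rotation = R,
        translation = as.vector(-R %*% transform@translation),
        residuals = transform@residuals, rms = transform@rms)
}

#' Build the AC-PC targeting coordinate system
#'
#' Constructs the coordinate frame used for surgical targeting: origin at
#' the midpoint of the anterior (AC) and posterior (PC) commissures, Y axis
#' the unit vector from PC toward AC, Z axis orthogonal to Y within the
#' plane spanned by the AC-PC line and a midsagittal reference point
#' (pointing toward that point), and X = Y x Z completing a right-handed
#' frame (positive toward the patient's right).
#'
#' @param ac,pc numeric(3) landmark positions in scanner/world mm.
#' @param midsagittal numeric(3) reference point off the AC-PC line,
#'   defining the X = 0 plane.
#' @return an [ACPCFrame-class].
#' @export
#' @examples
#' f <- buildAcpc(c(0, 12, 0), c(0, -12, 0), c(0, 0, 10))
#' acpcCoords(f, c(0, 12, 0))   # AC sits at (0, 12, 0) in AC-PC space
buildAcpc <- function(ac, pc, midsagittal) {
    ac <- as.numeric(ac); pc <- as.numeric(pc)
    midsagittal <- as.numeric(midsagittal)
    .stopIf(length(ac) != 3 || length(pc) != 3 || length(midsagittal) != 3,
            "ac, pc and midsagittal must be 3-D points")
    .stopIf(.euclid(ac, pc) < 1e-9, "AC and PC coincide")
    origin <- (ac + pc) / 2
    y <- (ac - pc) / .euclid(ac, pc)
    v <- midsagittal - origin
    zRaw <- v - sum(v * y) * y
    .stopIf(sqrt(sum(zRaw^2)) < 1e-9,
            "midsagittal point lies on the AC-PC line")
    z <- zRaw / sqrt(sum(zRaw^2))
    x <- c(y[2] * z[3] - y[3] * z[2],
           y[3] * z[1] - y[1] * z[3],
           y[1] * z[2] - y[2] * z[1])
    new("ACPCFrame", ac = ac, pc = pc, origin = origin,
        axes = cbind(x, y, z, deparse.level = 0))
}

#' Coordinates of world points in AC-PC space
#'
#' @param acpc an [ACPCFrame-class].
#' @param points numeric n x 3 matrix (or length-3 vector) in world mm.
#' @return (x, y, z) AC-PC coordinates, same shape as the input.
#' @export
acpcCoords <- function(acpc, points) {
    stopifnot(is(acpc, "ACPCFrame"))
    vec <- is.null(dim(points))
    p <- if (vec) matrix(points, 1) else as.matrix(points)
    out <- sweep(p, 2, acpc@origin) %*% acpc@axes
    colnames(out) <- c("x", "y", "z")
    if (vec) drop(out) else out
}

#' Compute a surgical target in AC-PC coordinates
#'
#' Places a target at the given offsets from the AC-PC midpoint, with the
#' sign of the lateral offset set by `side` (X positive toward the
#' patient's right, so left-side targets carry negative x internally).
#' The `withinProtocol` flag records whether the target lies inside the
#' stereotactic protocol window for the subthalamic nucleus:
#' |x| in \[10, 13\] mm, y in \[-2, -1\] mm, z in \[-6, -2\] mm, boundaries
#' inclusive.
#'
#' @param acpc an [ACPCFrame-class].
#' @param side `"left"` or `"right"`.
#' @param x lateral offset magnitude in mm (>= 0).
#' @param y,z anterior/posterior and vertical offsets in mm (signed).
#' @return a [TargetCoordinate-class].
#' @export
targetCoordinates <- function(acpc, side = c("left", "right"), x, y, z) {
    stopifnot(is(acpc, "ACPCFrame"))
    side <- match.arg(side)
    .stopIf(!all(is.finite(c(x, y, z))), "offsets must be finite")
    xs <- if (side == "left") -abs(x) else abs(x)
    coords <- c(x = xs, y = y, z = z)
    within <- abs(xs) >= 10 && abs(xs) <= 13 &&
        y >= -2 && y <= -1 && z >= -6 && z <= -2
    world <- acpc@origin + as.vector(acpc@axes %*% coords)
    new("TargetCoordinate", coords = coords, world = world,
        side = side, withinProtocol = within)
}

#' Fiducial and target registration error report
#'
#' Computes the standard error decomposition of frame registration:
#' per-mark fiducial localization error (FLE, the distance between the
#' detected and true mark position, converted to mm by the pixel spacing),
#' the fiducial registration error (FRE, the RMS residual of the fitted
#' transform), and the target registration error (TRE, the distance between
#' a target mapped through the transform and its true frame position).
#'
#' @param truth a [PhantomTruth-class] covering all matched labels (its
#'   `framePoints` order matches its `circles` order).
#' @param fiducials the matched [FiducialSet-class].
#' @param transform the fitted [FrameTransform-class].
#' @param spacing numeric(2), mm per px of the detection image.
#' @param targets optional named list; each element is
#'   `list(image = , frame = )`, the target position in image mm and its
#'   true frame mm position.
#' @return an [ErrorReport-class].
#' @export
evaluateErrors <- function(truth, fiducials, transform, spacing = c(1, 1),
                           targets = list()) {
    stopifnot(is(truth, "PhantomTruth"), is(fiducials, "FiducialSet"),
              is(transform, "FrameTransform"))
    m <- fiducials@matches
    idx <- match(m$label, truth@framePoints$label)
    .stopIf(anyNA(idx),
            "matched label(s) absent from truth: %s",
            paste(m$label[is.na(idx)], collapse = ", "))
    tc <- truth@circles[idx, , drop = FALSE]
    fle <- sqrt(((m$imageRow - tc$a) * spacing[1])^2 +
                ((m$imageCol - tc$b) * spacing[2])^2)
    names(fle) <- m$label
    tre <- vapply(targets, function(tg) {
        .euclid(applyTransform(transform, as.numeric(tg$image)),
                as.numeric(tg$frame))
    }, numeric(1))
    summ <- c(mean = mean(fle), sd = if (length(fle) > 1) stats::sd(fle) else 0,
              max = if (length(fle)) max(fle) else 0)
    new("ErrorReport", fle = fle, fre = transform@rms, tre = tre,
        summary = summ)
}
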