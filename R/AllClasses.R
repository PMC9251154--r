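#' @import methods
NULL

## ---------------------------------------------------------------------------
## Pixel coordinate convention, used everywhere in the package:
## 1-based (row, col), intensities indexed image[row, col], pixel centres at
## integer coordinates. A circle centre is (a, b) = (row, col) in pixels;
## physical positions are (row, col) * spacing in mm.
## ---------------------------------------------------------------------------

#' ImageSlice: a 2-D intensity grid with physical pixel spacing
#'
#' Lightweight container for one MR slice (or any grayscale image) together
#' with its per-axis pixel spacing in millimetres. Intensities are arbitrary
#' (typically 0--255 for the synthetic phantoms).
#'
#' @slot intensity numeric matrix of intensities, indexed `[row, col]`.
#' @slot spacing numeric length-2 vector, mm per pixel along (row, col).
#'
#' @aliases ImageSlice
#' @exportClass ImageSlice
setClass("ImageSlice",
         representation(intensity = "matrix", spacing = "numeric"))

setValidity("ImageSlice", function(object) {
    msg <- character()
    if (!is.numeric(object@intensity))
        msg <- c(msg, "intensity must be a numeric matrix")
    if (length(object@spacing) != 2L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be two positive finite numbers (mm/px)")
    if (any(!is.finite(object@intensity)))
        msg <- c(msg, "intensity must be finite-valued")
    if (length(msg)) msg else TRUE
})

#' @param intensity numeric matrix.
#' @param spacing numeric(2), mm per pixel (row, col). Default 1 mm isotropic.
#' @rdname ImageSlice-class
#' @export
ImageSlice <- function(intensity, spacing = c(1, 1)) {
    new("ImageSlice", intensity = as.matrix(intensity),
        spacing = as.numeric(spacing))
}

#' ImageVolume: a stack of slices with 3-D voxel spacing
#'
#' @slot intensity 3-D numeric array indexed `[row, col, slice]`.
#' @slot spacing numeric(3), mm per voxel along (row, col, slice).
#'
#' @aliases ImageVolume
#' @exportClass ImageVolume
setClass("ImageVolume",
         representation(intensity = "array", spacing = "numeric"))

setValidity("ImageVolume", function(object) {
    msg <- character()
    if (length(dim(object@intensity)) != 3L)
        msg <- c(msg, "intensity must be a 3-D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be three positive finite numbers (mm/voxel)")
    if (length(msg)) msg else TRUE
})

#' @param intensity 3-D numeric array.
#' @param spacing numeric(3), mm per voxel. Default 1 mm isotropic.
#' @rdname ImageVolume-class
#' @export
ImageVolume <- function(intensity, spacing = c(1, 1, 1)) {
    new("ImageVolume", intensity = intensity, spacing = as.numeric(spacing))
}

#' PhantomSpec: recipe for a synthetic fiducial phantom
#'
#' Describes a synthetic MRI-like slice (or, replicated, a volume): image
#' size and spacing, bright circular fiducials, bright line features, a
#' smooth background, and an additive noise model. Together with a seed the
#' spec fully determines the rendered image, so phantoms are reproducible
#' bit-for-bit.
#'
#' @slot width,height image size in pixels (width = columns, height = rows).
#' @slot spacing mm per pixel along (row, col).
#' @slot circles data.frame with columns `a`, `b` (centre row/col, px,
#'   possibly fractional), `r` (radius, px), `amplitude` (intensity above
#'   background), `thickness` (annulus thickness, px) and `filled` (logical;
#'   disc instead of annulus).
#' @slot lines data.frame with columns `theta` (radians in \[0, pi)), `rho`
#'   (px, signed normal distance rho = a cos(theta) + b sin(theta)),
#'   `amplitude`, `thickness`.
#' @slot background constant background intensity.
#' @slot gradientAmplitude peak-to-peak amplitude of a smooth diagonal ramp
#'   added to the background (models shading; 0 disables).
#' @slot noiseModel `"gaussian"` (additive) or `"rician"` (MR magnitude
#'   noise).
#' @slot noiseSigma noise standard deviation in intensity units; 0 disables.
#' @slot seed integer RNG seed used when noise is drawn.
#'
#' @aliases PhantomSpec
#' @exportClass PhantomSpec
setClass("PhantomSpec",
         representation(width = "integer", height = "integer",
                        spacing = "numeric",
                        circles = "data.frame", lines = "data.frame",
                        background = "numeric",
                        gradientAmplitude = "numeric",
                        noiseModel = "character", noiseSigma = "numeric",
                        seed = "integer"))

setValidity("PhantomSpec", function(object) {
    msg <- character()
    if (object@width < 8L || object@height < 8L)
        msg <- c(msg, "image must be at least 8x8 pixels")
    if (nrow(object@circles)) {
        cc <- object@circles
        if (any(cc$r < 2))
            msg <- c(msg, "circle radii must be >= 2 px")
        out <- cc$a - cc$r < 1 | cc$a + cc$r > object@height |
               cc$b - cc$r < 1 | cc$b + cc$r > object@width
        if (any(out))
            msg <- c(msg, sprintf(
                "circle(s) %s extend outside the image bounds",
                paste(which(out), collapse = ", ")))
    }
    if (nrow(object@lines) &&
        (any(object@lines$theta < 0) || any(object@lines$theta >= pi)))
        msg <- c(msg, "line theta must lie in [0, pi)")
    if (object@noiseSigma < 0)
        msg <- c(msg, "noiseSigma must be >= 0")
    if (!object@noiseModel %in% c("gaussian", "rician"))
        msg <- c(msg, "noiseModel must be 'gaussian' or 'rician'")
    if (length(object@spacing) != 2L || any(object@spacing <= 0))
        msg <- c(msg, "spacing must be two positive numbers")
    if (length(msg)) msg else TRUE
})

#' PhantomTruth: ground truth of a generated phantom
#'
#' One truth entry per generated feature, in generation order. For volume
#' phantoms the true AC and PC landmark positions (mm) and the template
#' frame coordinates (mm) of each fiducial are recorded as well.
#'
#' @slot circles data.frame (`a`, `b`, `r`) at sub-pixel precision.
#' @slot lines data.frame (`theta`, `rho`).
#' @slot ac,pc numeric(3) mm landmark positions, or numeric(0) for slices.
#' @slot framePoints data.frame (`label`, `x`, `y`, `z`) template mm
#'   coordinates of each fiducial (empty for plain slices).
#'
#' @aliases PhantomTruth
#' @exportClass PhantomTruth
setClass("PhantomTruth",
         representation(circles = "data.frame", lines = "data.frame",
                        ac = "numeric", pc = "numeric",
                        framePoints = "data.frame"))

#' EdgeMap: binary edge image plus gradient magnitudes
#'
#' @slot edges logical matrix, TRUE on edge pixels; same shape as the image.
#' @slot gradient numeric matrix of gradient magnitudes (kept for sub-pixel
#'   refinement and diagnostics).
#'
#' @aliases EdgeMap
#' @exportClass EdgeMap
setClass("EdgeMap",
         representation(edges = "matrix", gradient = "matrix"))

setValidity("EdgeMap", function(object) {
    msg <- character()
    if (!is.logical(object@edges))
        msg <- c(msg, "edges must be a logical matrix")
    if (!identical(dim(object@edges), dim(object@gradient)))
        msg <- c(msg, "edges and gradient must have identical dimensions")
    if (length(msg)) msg else TRUE
})

#' LineAccumulator: Hough vote array over (theta, rho)
#'
#' @slot votes integer matrix, rows = theta bins, cols = rho bins.
#' @slot theta numeric vector of theta bin centres (radians, in \[0, pi)).
#' @slot rho numeric vector of rho bin centres (px).
#'
#' @aliases LineAccumulator
#' @exportClass LineAccumulator
setClass("LineAccumulator",
         representation(votes = "matrix", theta = "numeric", rho = "numeric"))

#' CircleAccumulator: the 3-D Hough vote array A(a, b, r)
#'
#' The discretized circle parameter space: bin (i, j, k) counts edge-pixel
#' votes for a circle centred at row `aBins[i]`, col `bBins[j]` with radius
#' `rBins[k]`. `perimeter` records, per radius, how many centre-locus bins a
#' single edge pixel casts; it is used to normalize peak scores so large
#' circles are not favoured.
#'
#' @slot votes 3-D integer array indexed (a, b, r).
#' @slot aBins,bBins,rBins numeric bin-centre vectors.
#' @slot perimeter numeric, votes cast per edge pixel at each radius.
#'
#' @aliases CircleAccumulator
#' @exportClass CircleAccumulator
setClass("CircleAccumulator",
         representation(votes = "array", aBins = "numeric", bBins = "numeric",
                        rBins = "numeric", perimeter = "numeric"))

setValidity("CircleAccumulator", function(object) {
    d <- dim(object@votes)
    if (length(d) != 3L)
        return("votes must be a 3-D array")
    if (!identical(d, c(length(object@aBins), length(object@bBins),
                        length(object@rBins))))
        return("votes dimensions must match the bin vectors")
    if (length(object@perimeter) != length(object@rBins))
        return("perimeter must have one entry per radius bin")
    TRUE
})

#' FrameTemplate: labelled fiducial geometry of a stereotactic frame
#'
#' @slot points data.frame with columns `label`, `x`, `y`, `z` (mm).
#' @slot anchors character(2): the two labels defining the reference axis
#'   (the anchor pair "A", "B"); their separation must be the unique maximum
#'   inter-point distance so they can be recognised among detections.
#' @slot collinearGroups list of character vectors: label sets expected to be
#'   collinear (e.g. the marks along one frame rod).
#'
#' @aliases FrameTemplate
#' @exportClass FrameTemplate
setClass("FrameTemplate",
         representation(points = "data.frame", anchors = "character",
                        collinearGroups = "list"))

setValidity("FrameTemplate", function(object) {
    msg <- character()
    p <- object@points
    if (!all(c("label", "x", "y", "z") %in% names(p)))
        msg <- c(msg, "points needs columns label, x, y, z")
    else {
        if (anyDuplicated(p$label))
            msg <- c(msg, "labels must be unique")
        if (length(object@anchors) != 2L ||
            !all(object@anchors %in% p$label))
            msg <- c(msg, "anchors must be two labels present in points")
        bad <- !vapply(object@collinearGroups,
                       function(g) all(g %in% p$label), logical(1))
        if (any(bad))
            msg <- c(msg, "collinear groups refer to unknown labels")
    }
    if (length(msg)) msg else TRUE
})

#' FiducialSet: detections matched and labelled against a template
#'
#' @slot matches data.frame: `label`, image coordinates `imageRow`,
#'   `imageCol` (px, sub-pixel), template coordinates `templateX`,
#'   `templateY` (mm), and the per-match alignment `residual` (template
#'   units).
#' @slot unmatchedDetections data.frame of detections left unlabelled.
#' @slot unmatchedLabels character: template labels with no detection.
#'
#' @aliases FiducialSet
#' @exportClass FiducialSet
setClass("FiducialSet",
         representation(matches = "data.frame",
                        unmatchedDetections = "data.frame",
                        unmatchedLabels = "character"))

setValidity("FiducialSet", function(object) {
    m <- object@matches
    if (nrow(m) && anyDuplicated(m$label))
        return("each label may appear at most once among matches")
    TRUE
})

#' FrameTransform: rigid map from image mm space to frame mm space
#'
#' A rotation plus translation, `q = R p + t`, fitted by orthogonal
#' Procrustes. `rms` is the fiducial registration error (FRE).
#'
#' @slot rotation d x d rotation matrix (d = 2 or 3), orthonormal, det +1.
#' @slot translation numeric(d), mm.
#' @slot residuals numeric, per-point fit residuals in mm.
#' @slot rms root-mean-square residual (FRE), mm.
#'
#' @aliases FrameTransform
#' @exportClass FrameTransform
setClass("FrameTransform",
         representation(rotation = "matrix", translation = "numeric",
                        residuals = "numeric", rms = "numeric"))

setValidity("FrameTransform", function(object) {
    R <- object@rotation
    d <- nrow(R)
    if (!d %in% 2:3 || ncol(R) != d)
        return("rotation must be 2x2 or 3x3")
    if (length(object@translation) != d)
        return("translation dimension must match the rotation")
    if (max(abs(crossprod(R) - diag(d))) > 1e-9)
        return("rotation must be orthonormal (to 1e-9)")
    if (abs(det(R) - 1) > 1e-9)
        return("rotation must have determinant +1 (to 1e-9)")
    TRUE
})

#' ACPCFrame: the AC-PC targeting coordinate system
#'
#' Origin at the midpoint of the anterior and posterior commissures, Y axis
#' along PC -> AC, Z orthogonal to Y within the midsagittal plane, X
#' completing a right-handed frame (positive toward the patient's right).
#'
#' @slot ac,pc numeric(3) landmark positions in scanner/world mm.
#' @slot origin numeric(3), midpoint of AC and PC.
#' @slot axes 3 x 3 matrix whose columns are the unit X, Y, Z axes.
#'
#' @aliases ACPCFrame
#' @exportClass ACPCFrame
setClass("ACPCFrame",
         representation(ac = "numeric", pc = "numeric", origin = "numeric",
                        axes = "matrix"))

setValidity("ACPCFrame", function(object) {
    if (length(object@ac) != 3L || length(object@pc) != 3L)
        return("ac and pc must be 3-D points")
    if (sqrt(sum((object@ac - object@pc)^2)) == 0)
        return("AC and PC must be distinct")
    A <- object@axes
    if (max(abs(crossprod(A) - diag(3))) > 1e-9)
        return("axes must be orthonormal")
    if (abs(det(A) - 1) > 1e-9)
        return("axes must form a right-handed frame")
    TRUE
})

#' TargetCoordinate: a surgical target in AC-PC coordinates
#'
#' @slot coords numeric(3): (x, y, z) mm in AC-PC space, x signed by side.
#' @slot world numeric(3): the same point in scanner/world mm.
#' @slot side `"left"` or `"right"`.
#' @slot withinProtocol TRUE iff |x| in \[10, 13\], y in \[-2, -1\] and
#'   z in \[-6, -2\] mm (boundaries inclusive) -- the stereotactic targeting
#'   protocol window for the subthalamic nucleus.
#'
#' @aliases TargetCoordinate
#' @exportClass TargetCoordinate
setClass("TargetCoordinate",
         representation(coords = "numeric", world = "numeric",
                        side = "character", withinProtocol = "logical"))

#' ErrorReport: fiducial and target registration error statistics
#'
#' @slot fle named numeric: fiducial localization error per mark, mm.
#' @slot fre fiducial registration error (RMS transform residual), mm.
#' @slot tre named numeric: target registration error per requested target,
#'   mm.
#' @slot summary named numeric: mean, sd, max of the FLEs.
#'
#' @aliases ErrorReport
#' @exportClass ErrorReport
setClass("ErrorReport",
         representation(fle = "numeric", fre = "numeric", tre = "numeric",
                        summary = "numeric"))

setValidity("ErrorReport", function(object) {
    if (any(object@fle < 0) || any(object@fre < 0) || any(object@tre < 0))
        return("errors must be non-negative")
    TRUE
})

#' EfficacyThresholds: improvement-rate class boundaries
#'
#' Cut-offs (percent improvement) separating the three efficacy classes:
#' rate >= `markedlyEffectiveMin` is markedly effective, rate in
#' \[`improvedMin`, `markedlyEffectiveMin`) is improved, anything lower is
#' ineffective. Boundaries are inclusive on the left.
#'
#' @slot markedlyEffectiveMin percent, default 50.
#' @slot improvedMin percent, default 20.
#'
#' @aliases EfficacyThresholds
#' @exportClass EfficacyThresholds
setClass("EfficacyThresholds",
         representation(markedlyEffectiveMin = "numeric",
                        improvedMin = "numeric"))

setValidity("EfficacyThresholds", function(object) {
    if (!(object@improvedMin > 0 &&
          object@improvedMin < object@markedlyEffectiveMin &&
          object@markedlyEffectiveMin <= 100))
        return("need 0 < improvedMin < markedlyEffectiveMin <= 100")
    TRUE
})

#' @param markedlyEffectiveMin,improvedMin percent improvement cut-offs.
#' @rdname EfficacyThresholds-class
#' @export
efficacyThresholds <- function(markedlyEffectiveMin = 50, improvedMin = 20) {
    new("EfficacyThresholds",
        markedlyEffectiveMin = as.numeric(markedlyEffectiveMin),
        improvedMin = as.numeric(improvedMin))
}

#' EfficacyTable: per-group efficacy counts and percentages
#'
#' @slot counts integer matrix, rows = groups, cols = efficacy classes.
#' @slot percent numeric matrix of row percentages (one decimal place).
#'
#' @aliases EfficacyTable
#' @exportClass EfficacyTable
setClass("EfficacyTable",
         representation(counts = "matrix", percent = "matrix"))

setValidity("EfficacyTable", function(object) {
    if (!identical(dim(object@counts), dim(object@percent)))
        return("counts and percent must have the same shape")
    rp <- rowSums(object@percent)
    if (any(abs(rp - 100) > 0.1))
        return("row percentages must sum to 100 within 0.1")
    TRUE
})
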