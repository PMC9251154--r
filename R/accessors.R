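#' Accessors for stereomark objects
#'
#' Small accessor functions exposing the slots of the package's S4 classes;
#' user code should prefer these over `@`.
#'
#' @param x an object of the documented class.
#' @param object an object (for `residuals`).
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("intensity", "ImageSlice", function(x) x@intensity)

#' @rdname accessors
#' @export
setMethod("intensity", "ImageVolume", function(x) x@intensity)

#' @rdname accessors
#' @export
setMethod("spacing", "ImageSlice", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("spacing", "ImageVolume", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("edges", "EdgeMap", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("gradientMap", "EdgeMap", function(x) x@gradient)

#' @rdname accessors
#' @export
setMethod("votes", "LineAccumulator", function(x) x@votes)

#' @rdname accessors
#' @export
setMethod("votes", "CircleAccumulator", function(x) x@votes)

#' @rdname accessors
#' @export
setMethod("matches", "FiducialSet", function(x) x@matches)

#' @rdname accessors
#' @export
setMethod("unmatchedDetections", "FiducialSet", function(x) x@unmatchedDetections)

#' @rdname accessors
#' @export
setMethod("unmatchedLabels", "FiducialSet", function(x) x@unmatchedLabels)

#' @rdname accessors
#' @export
setMethod("rotation", "FrameTransform", function(x) x@rotation)

#' @rdname accessors
#' @export
setMethod("translation", "FrameTransform", function(x) x@translation)

#' @rdname accessors
#' @importFrom stats residuals
#' @export
setMethod("residuals", "FrameTransform", function(object, ...) object@residuals)

#' @rdname accessors
#' @export
setMethod("rmsError", "FrameTransform", function(x) x@rms)

#' @rdname accessors
#' @export
setMethod("coords", "TargetCoordinate", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("withinProtocol", "TargetCoordinate", function(x) x@withinProtocol)

#' @rdname accessors
#' @export
setMethod("counts", "EfficacyTable", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("percentages", "EfficacyTable", function(x) x@percent)

#' @rdname accessors
#' @export
setMethod("framePoints", "PhantomTruth", function(x) x@framePoints)

#' @rdname accessors
#' @export
setMethod("trueCircles", "PhantomTruth", function(x) x@circles)

#' @rdname accessors
#' @export
setMethod("trueLines", "PhantomTruth", function(x) x@lines)

#' @rdname accessors
#' @export
setMethod("dim", "ImageSlice", function(x) dim(x@intensity))

#' @rdname accessors
#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@intensity))
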