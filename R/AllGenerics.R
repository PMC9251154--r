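#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("gradientMap", function(x) standardGeneric("gradientMap"))

#' @rdname accessors
#' @export
setGeneric("votes", function(x) standardGeneric("votes"))

#' @rdname accessors
#' @export
setGeneric("matches", function(x) standardGeneric("matches"))

#' @rdname accessors
#' @export
setGeneric("unmatchedDetections", function(x) standardGeneric("unmatchedDetections"))

#' @rdname accessors
#' @export
setGeneric("unmatchedLabels", function(x) standardGeneric("unmatchedLabels"))

#' @rdname accessors
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))

#' @rdname accessors
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))

#' @rdname accessors
#' @export
setGeneric("rmsError", function(x) standardGeneric("rmsError"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("withinProtocol", function(x) standardGeneric("withinProtocol"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("percentages", function(x) standardGeneric("percentages"))

#' @rdname accessors
#' @export
setGeneric("framePoints", function(x) standardGeneric("framePoints"))

#' @rdname accessors
#' @export
setGeneric("trueCircles", function(x) standardGeneric("trueCircles"))

#' @rdname accessors
#' @export
setGeneric("trueLines", function(x) standardGeneric("trueLines"))
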