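setMethod("show", "ImageSlice", function(object) {
    d <- dim(object@intensity)
    cat(sprintf("ImageSlice: %d x %d px, spacing %.3g x %.3g mm, range [%.3g, %.3g]\n",
                d[1], d[2], object@spacing[1], object@spacing[2],
                min(object@intensity), max(object@intensity)))
})

setMethod("show", "ImageVolume", function(object) {
    d <- dim(object@intensity)
    cat(sprintf("ImageVolume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
                d[1], d[2], d[3],
                object@spacing[1], object@spacing[2], object@spacing[3]))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf("PhantomSpec: %d x %d px, %d circle(s), %d line(s), %s noise sigma=%.3g, seed=%d\n",
                object@height, object@width, nrow(object@circles),
                nrow(object@lines), object@noiseModel, object@noiseSigma,
                object@seed))
})

setMethod("show", "PhantomTruth", function(object) {
    cat(sprintf("PhantomTruth: %d circle(s), %d line(s)%s\n",
                nrow(object@circles), nrow(object@lines),
                if (length(object@ac)) ", AC/PC recorded" else ""))
})

setMethod("show", "EdgeMap", function(object) {
    cat(sprintf("EdgeMap: %d x %d, %d edge pixel(s)\n",
                nrow(object@edges), ncol(object@edges), sum(object@edges)))
})

setMethod("show", "LineAccumulator", function(object) {
    cat(sprintf("LineAccumulator: %d theta x %d rho bins, %d total vote(s)\n",
                length(object@theta), length(object@rho), sum(object@votes)))
})

setMethod("show", "CircleAccumulator", function(object) {
    cat(sprintf("CircleAccumulator: A(a,b,r) = %d x %d x %d bins, %d total vote(s)\n",
                length(object@aBins), length(object@bBins),
                length(object@rBins), sum(object@votes)))
})

setMethod("show", "FrameTemplate", function(object) {
    cat(sprintf("FrameTemplate: %d labelled point(s), anchors %s-%s, %d collinear group(s)\n",
                nrow(object@points), object@anchors[1], object@anchors[2],
                length(object@collinearGroups)))
})

setMethod("show", "FiducialSet", function(object) {
    cat(sprintf("FiducialSet: %d match(es), %d unmatched detection(s), %d unmatched label(s)\n",
                nrow(object@matches), nrow(object@unmatchedDetections),
                length(object@unmatchedLabels)))
    if (nrow(object@matches)) {
        print(object@matches, digits = 4)
    }
})

setMethod("show", "FrameTransform", function(object) {
    d <- nrow(object@rotation)
    cat(sprintf("FrameTransform (%d-D rigid): FRE (RMS) = %.4g mm\n", d, object@rms))
    cat("rotation:\n"); print(round(object@rotation, 6))
    cat("translation (mm):", format(round(object@translation, 6)), "\n")
})

setMethod("show", "ACPCFrame", function(object) {
    cat(sprintf("ACPCFrame: origin (%.2f, %.2f, %.2f) mm, |AC-PC| = %.2f mm\n",
                object@origin[1], object@origin[2], object@origin[3],
                sqrt(sum((object@ac - object@pc)^2))))
})

setMethod("show", "TargetCoordinate", function(object) {
    cat(sprintf("TargetCoordinate (%s): AC-PC (%.2f, %.2f, %.2f) mm, %s protocol\n",
                object@side, object@coords[1], object@coords[2],
                object@coords[3],
                if (object@withinProtocol) "within" else "OUTSIDE"))
})

setMethod("show", "ErrorReport", function(object) {
    cat(sprintf("ErrorReport: FRE = %.4g mm; FLE mean %.4g, sd %.4g, max %.4g mm (n = %d)\n",
                object@fre, object@summary["mean"], object@summary["sd"],
                object@summary["max"], length(object@fle)))
    if (length(object@tre))
        cat("TRE (mm):", paste(names(object@tre),
                               format(round(object@tre, 4)), collapse = "; "), "\n")
})

setMethod("show", "EfficacyThresholds", function(object) {
    cat(sprintf("EfficacyThresholds: markedly effective >= %g%%, improved >= %g%%\n",
                object@markedlyEffectiveMin, object@improvedMin))
})

setMethod("show", "EfficacyTable", function(object) {
    cat("EfficacyTable (counts):\n"); print(object@counts)
    cat("row percentages:\n"); print(object@percent)
})
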