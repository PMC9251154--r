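## 16-bit intensity scale used when writing slices to PNG/TIFF.
.SLICE_MAX <- 65535

#' Read and write image slices
#'
#' Slices are stored as grayscale PNG (8-bit) or, when the file name ends
#' in `.tif`/`.tiff` and the `tiff` package is available, 16-bit TIFF --
#' use TIFF when quantization matters. Intensities are scaled into
#' \[0, 1\] on write using `maxIntensity` and rescaled back on read, so a
#' round trip preserves values up to the format's bit depth. Pixel spacing
#' is not representable in these formats and must be supplied on read.
#'
#' @param path file path (`.png`, `.tif` or `.tiff`).
#' @param image an [ImageSlice-class] or matrix.
#' @param spacing mm per pixel to attach on read.
#' @param maxIntensity full-scale intensity (default 255).
#' @return `readSliceImage`: an `ImageSlice`; `writeSliceImage`: the path,
#'   invisibly.
#' @export
readSliceImage <- function(path, spacing = c(1, 1), maxIntensity = 255) {
    ext <- tolower(tools::file_ext(path))
    m <- if (ext %in% c("tif", "tiff")) {
        .stopIf(!requireNamespace("tiff", quietly = TRUE),
                "the 'tiff' package is needed for TIFF files")
        tiff::readTIFF(path)
    } else {
        png::readPNG(path)
    }
    if (length(dim(m)) == 3L) m <- m[, , 1]
    ImageSlice(m * maxIntensity, spacing)
}

#' @rdname readSliceImage
#' @export
writeSliceImage <- function(image, path, maxIntensity = 255) {
    m <- if (is(image, "ImageSlice")) image@intensity else image
    m <- pmin(pmax(m / maxIntensity, 0), 1)
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
        .stopIf(!requireNamespace("tiff", quietly = TRUE),
                "the 'tiff' package is needed for TIFF files")
        tiff::writeTIFF(m, path, bits.per.sample = 16L)
    } else {
        png::writePNG(m, path)
    }
    invisible(path)
}

#' Read and write image volumes as NIfTI-1
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param volume an [ImageVolume-class].
#' @return `readVolumeImage`: an `ImageVolume` with spacing taken from the
#'   NIfTI header; `writeVolumeImage`: the path, invisibly.
#' @export
readVolumeImage <- function(path) {
    img <- RNifti::readNifti(path)
    ImageVolume(array(as.numeric(img), dim = dim(img)),
                RNifti::pixdim(img)[1:3])
}

#' @rdname readVolumeImage
#' @export
writeVolumeImage <- function(volume, path) {
    stopifnot(is(volume, "ImageVolume"))
    img <- RNifti::asNifti(volume@intensity)
    RNifti::pixdim(img) <- volume@spacing
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Write phantom ground truth as a JSON sidecar
#'
#' @param truth a [PhantomTruth-class].
#' @param path output JSON path.
#' @return the path, invisibly. `readPhantomTruth` returns the
#'   `PhantomTruth`.
#' @export
writePhantomTruth <- function(truth, path) {
    stopifnot(is(truth, "PhantomTruth"))
    jsonlite::write_json(
        list(circles = truth@circles, lines = truth@lines,
             ac = truth@ac, pc = truth@pc, framePoints = truth@framePoints),
        path, digits = NA, auto_unbox = FALSE)
    invisible(path)
}

#' @rdname writePhantomTruth
#' @export
readPhantomTruth <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    asDf <- function(d, cols) {
        if (is.null(d) || !length(d)) {
            out <- as.data.frame(stats::setNames(rep(list(numeric()),
                                                     length(cols)), cols))
            return(out)
        }
        as.data.frame(d)[cols]
    }
    new("PhantomTruth",
        circles = asDf(x$circles, c("a", "b", "r")),
        lines = asDf(x$lines, c("theta", "rho")),
        ac = as.numeric(unlist(x$ac)), pc = as.numeric(unlist(x$pc)),
        framePoints = if (is.null(x$framePoints) || !length(x$framePoints))
            data.frame(label = character(), x = numeric(), y = numeric(),
                       z = numeric())
        else as.data.frame(x$framePoints))
}

#' Read a frame template from YAML
#'
#' Expected layout:
#' ```yaml
#' anchors: [A, B]
#' points:
#'   - {label: A, x: 0, y: 0, z: 0}
#'   - {label: B, x: 100, y: 0, z: 0}
#' collinear:
#'   - [A, M1, B]
#' ```
#'
#' @param path YAML file path.
#' @param template a [FrameTemplate-class] (for writing).
#' @return a `FrameTemplate` / the path, invisibly.
#' @export
readFrameTemplate <- function(path) {
    y <- yaml::read_yaml(path)
    pts <- do.call(rbind, lapply(y$points, function(p)
        data.frame(label = as.character(p$label), x = p$x, y = p$y,
                   z = if (is.null(p$z)) 0 else p$z)))
    frameTemplate(pts, unlist(y$anchors),
                  if (is.null(y$collinear)) list()
                  else lapply(y$collinear, unlist))
}

#' @rdname readFrameTemplate
#' @export
writeFrameTemplate <- function(template, path) {
    stopifnot(is(template, "FrameTemplate"))
    p <- template@points
    yaml::write_yaml(list(
        anchors = as.list(template@anchors),
        points = lapply(seq_len(nrow(p)), function(i)
            list(label = p$label[i], x = p$x[i], y = p$y[i], z = p$z[i])),
        collinear = lapply(template@collinearGroups, as.list)), path)
    invisible(path)
}

#' Write detected marks / matches as JSON
#'
#' @param marks a data.frame of detections (from [detectCircles()]) or a
#'   [FiducialSet-class].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeMarks <- function(marks, path) {
    if (is(marks, "FiducialSet"))
        marks <- list(matches = marks@matches,
                      unmatchedDetections = marks@unmatchedDetections,
                      unmatchedLabels = marks@unmatchedLabels)
    jsonlite::write_json(marks, path, digits = NA, dataframe = "rows")
    invisible(path)
}

#' Read an outcome cohort CSV
#'
#' Columns: `patientId`, `group`, `updrsPre`, `updrsPost`.
#'
#' @param path CSV file path.
#' @return validated data.frame of outcome records.
#' @export
readOutcomeCohort <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    .stopIf(!all(c("patientId", "group", "updrsPre", "updrsPost") %in%
                 names(d)),
            "cohort CSV needs columns patientId, group, updrsPre, updrsPost")
    .stopIf(any(d$updrsPre <= 0), "updrsPre must be > 0 for every record")
    .stopIf(any(d$updrsPost < 0), "updrsPost must be >= 0")
    d
}
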