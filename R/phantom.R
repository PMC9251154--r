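#' Describe a synthetic fiducial phantom
#'
#' Builds a validated [PhantomSpec-class] for the synthetic phantom
#' generator. The phantom emulates a positioning MR slice: a smooth
#' background, bright circular fiducial mark points (annuli by default, the
#' geometry Hough circle detection keys on; optionally filled discs), bright
#' line features (frame rods), and additive Gaussian or Rician noise.
#'
#' @param width,height image size in pixels (columns, rows).
#' @param spacing numeric(2), mm per pixel along (row, col).
#' @param circles data.frame (or NULL) with columns `a`, `b`, `r` and
#'   optionally `amplitude` (default 150), `thickness` (default 3) and
#'   `filled` (default FALSE). Centres may be fractional for sub-pixel
#'   ground truth.
#' @param lines data.frame (or NULL) with columns `theta`, `rho` and
#'   optionally `amplitude` (default 120) and `thickness` (default 2).
#'   The line is the locus a*cos(theta) + b*sin(theta) = rho in (row, col)
#'   pixel coordinates.
#' @param background constant background intensity (default 20).
#' @param gradientAmplitude amplitude of a smooth diagonal shading ramp
#'   (default 0).
#' @param noiseModel `"gaussian"` or `"rician"`.
#' @param noiseSigma noise sd in intensity units (0--255 scale typical).
#' @param seed integer seed controlling the noise draw.
#'
#' @return a `PhantomSpec`.
#' @seealso [makePhantomSlice()], [makePhantomVolume()]
#' @export
#' @examples
#' spec <- phantomSpec(circles = data.frame(a = 60, b = 70, r = 12))
#' sl <- makePhantomSlice(spec)
#' sl$image
phantomSpec <- function(width = 128, height = 128, spacing = c(1, 1),
                        circles = NULL, lines = NULL,
                        background = 20, gradientAmplitude = 0,
                        noiseModel = c("gaussian", "rician"),
                        noiseSigma = 0, seed = 1L) {
    noiseModel <- match.arg(noiseModel)
    circles <- .completeCircles(circles)
    lines <- .completeLines(lines)
    new("PhantomSpec", width = as.integer(width), height = as.integer(height),
        spacing = as.numeric(spacing), circles = circles, lines = lines,
        background = as.numeric(background),
        gradientAmplitude = as.numeric(gradientAmplitude),
        noiseModel = noiseModel, noiseSigma = as.numeric(noiseSigma),
        seed = as.integer(seed))
}

.completeCircles <- function(circles) {
    if (is.null(circles) || nrow(as.data.frame(circles)) == 0L)
        return(data.frame(a = numeric(), b = numeric(), r = numeric(),
                          amplitude = numeric(), thickness = numeric(),
                          filled = logical()))
    circles <- as.data.frame(circles)
    .stopIf(!all(c("a", "b", "r") %in% names(circles)),
            "circles needs columns a, b, r")
    if (is.null(circles$amplitude)) circles$amplitude <- 150
    if (is.null(circles$thickness)) circles$thickness <- 3
    if (is.null(circles$filled)) circles$filled <- FALSE
    circles[c("a", "b", "r", "amplitude", "thickness", "filled")]
}

.completeLines <- function(lines) {
    if (is.null(lines) || nrow(as.data.frame(lines)) == 0L)
        return(data.frame(theta = numeric(), rho = numeric(),
                          amplitude = numeric(), thickness = numeric()))
    lines <- as.data.frame(lines)
    .stopIf(!all(c("theta", "rho") %in% names(lines)),
            "lines needs columns theta, rho")
    if (is.null(lines$amplitude)) lines$amplitude <- 120
    if (is.null(lines$thickness)) lines$thickness <- 2
    lines[c("theta", "rho", "amplitude", "thickness")]
}

## Noise-free render of a spec: background + ramp + features, anti-aliased
## with a linear 1-px coverage profile at feature borders.
.renderClean <- function(spec) {
    nr <- spec@height; nc <- spec@width
    R <- matrix(seq_len(nr), nr, nc)
    C <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    img <- matrix(spec@background, nr, nc)
    if (spec@gradientAmplitude != 0)
        img <- img + spec@gradientAmplitude * ((R - 1) / (nr - 1) +
                                               (C - 1) / (nc - 1)) / 2
    cc <- spec@circles
    for (i in seq_len(nrow(cc))) {
        d <- sqrt((R - cc$a[i])^2 + (C - cc$b[i])^2)
        prof <- if (cc$filled[i]) {
            pmin(pmax(cc$r[i] + 0.5 - d, 0), 1)
        } else {
            pmin(pmax(cc$thickness[i] / 2 + 0.5 - abs(d - cc$r[i]), 0), 1)
        }
        img <- img + cc$amplitude[i] * prof
    }
    ll <- spec@lines
    for (i in seq_len(nrow(ll))) {
        d <- abs(R * cos(ll$theta[i]) + C * sin(ll$theta[i]) - ll$rho[i])
        img <- img + ll$amplitude[i] *
            pmin(pmax(ll$thickness[i] / 2 + 0.5 - d, 0), 1)
    }
    img
}

.addNoise <- function(img, model, sigma) {
    if (sigma == 0) return(img)
    n <- length(img)
    if (model == "gaussian") {
        img + matrix(stats::rnorm(n, sd = sigma), nrow(img))
    } else {
        ## Rician: magnitude of a complex signal with iid Gaussian channels
        re <- img + matrix(stats::rnorm(n, sd = sigma), nrow(img))
        im <- matrix(stats::rnorm(n, sd = sigma), nrow(img))
        sqrt(re^2 + im^2)
    }
}

#' Generate a synthetic phantom slice with ground truth
#'
#' Renders the features described by a [PhantomSpec-class] over the
#' background, adds noise under the spec's model and seed, and returns both
#' the image and a [PhantomTruth-class] listing every rendered feature.
#' Identical spec and seed give bit-identical output.
#'
#' @param spec a `PhantomSpec`.
#' @return list with elements `image` ([ImageSlice-class]) and `truth`
#'   ([PhantomTruth-class]).
#' @export
makePhantomSlice <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    clean <- .renderClean(spec)
    img <- .withSeed(spec@seed,
                     .addNoise(clean, spec@noiseModel, spec@noiseSigma))
    truth <- new("PhantomTruth",
                 circles = spec@circles[c("a", "b", "r")],
                 lines = spec@lines[c("theta", "rho")],
                 ac = numeric(), pc = numeric(),
                 framePoints = data.frame(label = character(),
                                          x = numeric(), y = numeric(),
                                          z = numeric()))
    list(image = ImageSlice(img, spec@spacing), truth = truth)
}

#' Generate a synthetic phantom volume with AC/PC ground truth
#'
#' Stacks `nSlices` renders of the spec (fiducials replicated at the same
#' template in-plane positions on every slice, as frame rods pierce all
#' slices), draws independent noise per slice from the spec seed, and
#' records the true AC and PC landmark positions in mm. Physical coordinates
#' are (row, col, slice) * spacing mm; `framePoints` holds the template mm
#' position of each fiducial at the volume's central slice.
#'
#' @param spec a `PhantomSpec`.
#' @param nSlices number of slices, >= 3.
#' @param sliceSpacing mm between slices (default 1).
#' @param ac,pc 3-D mm positions of the anterior/posterior commissures
#'   recorded as ground truth (defaults place them near the volume centre).
#' @return list with `image` ([ImageVolume-class]) and `truth`
#'   ([PhantomTruth-class]).
#' @export
makePhantomVolume <- function(spec, nSlices = 8, sliceSpacing = 1,
                              ac = NULL, pc = NULL) {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    .stopIf(nSlices < 3, "a volume needs at least 3 slices (got %d)", nSlices)
    .stopIf(length(sliceSpacing) != 1L || sliceSpacing <= 0,
            "sliceSpacing must be one positive number")
    ctr <- c(spec@height / 2 * spec@spacing[1],
             spec@width / 2 * spec@spacing[2],
             (nSlices + 1) / 2 * sliceSpacing)
    if (is.null(ac)) ac <- ctr + c(0, 12, 0)
    if (is.null(pc)) pc <- ctr - c(0, 12, 0)
    .stopIf(length(ac) != 3L || length(pc) != 3L,
            "ac and pc must be 3-D mm points")
    clean <- .renderClean(spec)
    vol <- .withSeed(spec@seed, {
        arr <- array(0, dim = c(spec@height, spec@width, nSlices))
        for (k in seq_len(nSlices))
            arr[, , k] <- .addNoise(clean, spec@noiseModel, spec@noiseSigma)
        arr
    })
    cc <- spec@circles
    fp <- data.frame(label = if (nrow(cc)) sprintf("M%d", seq_len(nrow(cc)))
                             else character(),
                     x = cc$a * spec@spacing[1],
                     y = cc$b * spec@spacing[2],
                     z = rep((nSlices + 1) / 2 * sliceSpacing, nrow(cc)))
    truth <- new("PhantomTruth",
                 circles = cc[c("a", "b", "r")],
                 lines = spec@lines[c("theta", "rho")],
                 ac = as.numeric(ac), pc = as.numeric(pc),
                 framePoints = fp)
    list(image = ImageVolume(vol, c(spec@spacing, sliceSpacing)),
         truth = truth)
}

#' Generate a synthetic pre/post UPDRS cohort with exact efficacy counts
#'
#' Creates a two-group cohort of Parkinson's disease outcome records whose
#' improvement rates `(pre - post) / pre * 100` fall inside the requested
#' efficacy-class bands, with exactly the requested number of patients per
#' class. Class bands are those of [classifyOutcome()]; rates are drawn
#' with a safety margin from the class boundaries so that rounding post
#' scores to integers never crosses a boundary.
#'
#' @param nObs,nCtl group sizes (observation / control).
#' @param obsCounts,ctlCounts integer(3): patients per class, in the order
#'   (markedly effective, ineffective, improved); each must sum to its
#'   group size.
#' @param thresholds an [EfficacyThresholds-class] (defaults 50 / 20).
#' @param seed integer RNG seed; identical arguments and seed reproduce the
#'   cohort exactly.
#' @return data.frame with columns `patientId`, `group`
#'   (`"observation"`/`"control"`), `updrsPre`, `updrsPost`.
#' @export
#' @examples
#' coh <- makeOutcomeCohort(40, 40, c(37, 1, 2), c(35, 2, 3), seed = 7)
#' tabulateOutcomes(coh)
makeOutcomeCohort <- function(nObs, nCtl, obsCounts, ctlCounts,
                              thresholds = efficacyThresholds(), seed = 1L) {
    stopifnot(is(thresholds, "EfficacyThresholds"))
    .checkCounts <- function(counts, n, what) {
        .stopIf(length(counts) != 3L || any(counts < 0) ||
                any(counts != round(counts)),
                "%s must be three non-negative integers", what)
        .stopIf(sum(counts) != n,
                "%s sum to %d but the group size is %d", what,
                sum(counts), n)
    }
    .checkCounts(obsCounts, nObs, "obsCounts")
    .checkCounts(ctlCounts, nCtl, "ctlCounts")
    m <- thresholds@markedlyEffectiveMin
    i <- thresholds@improvedMin
    margin <- 3
    bands <- list(markedlyEffective = c(m + margin, 97),
                  ineffective = c(-25, i - margin),
                  improved = c(i + margin, m - margin))
    .withSeed(seed, {
        gen <- function(counts, group, offset) {
            cls <- rep(names(bands), counts)
            n <- length(cls)
            pre <- sample(40:90, n, replace = TRUE)
            rate <- vapply(cls, function(k)
                stats::runif(1, bands[[k]][1], bands[[k]][2]), numeric(1))
            post <- pmax(round(pre * (1 - rate / 100)), 0)
            data.frame(patientId = sprintf("%s%03d", toupper(substr(group, 1, 1)),
                                           offset + seq_len(n)),
                       group = group, updrsPre = pre, updrsPost = post,
                       stringsAsFactors = FALSE)
        }
        rbind(gen(obsCounts, "observation", 0L),
              gen(ctlCounts, "control", 0L))
    })
}
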