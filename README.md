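# stereomark

Fiducial mark-point localization and stereotactic targeting for MR images.

Stereotactic surgery for Parkinson's disease plans a trajectory to a
deep-brain target (typically the subthalamic nucleus, STN) from a
positioning MRI acquired with a rigid frame on the patient's head. The
frame's fiducial *mark points* — bright ring markers and rods — have known
frame coordinates, so finding them in the image and fitting the rigid map
between the two spaces turns anatomical positions into frame coordinates
for targeting. `stereomark` implements that pipeline for people building
or validating such positioning software:

* **Phantoms** — `phantomSpec()`, `makePhantomSlice()`,
  `makePhantomVolume()`, `makeOutcomeCohort()`: deterministic synthetic
  slices/volumes with sub-pixel ground truth, and synthetic two-group
  UPDRS cohorts with exact efficacy-class counts.
* **Preprocessing** — `denoiseWavelet()` (separable periodized Daubechies
  DWT, soft shrinkage at the universal threshold
  `sigma_hat * sqrt(2 log N)` with `sigma_hat = median(|HH1|)/0.6745`),
  `snr()`, `detectEdges()` (Canny-style gradient + hysteresis).
* **Hough detection** — `houghLineAccumulate()`/`houghLinePeaks()` over
  the normal line parameterization `a cos(theta) + b sin(theta) = rho`;
  `houghCircleAccumulate()`/`houghCirclePeaks()` over the 3-D accumulator
  `A(a, b, r)` with perimeter-normalized scores; `refineCenter()` for
  sub-pixel centres and radii; `detectCircles()` for the one-call
  pipeline.
* **Matching** — `frameTemplate()`, `groupCollinear()`, `matchMarks()`:
  anchor-pair recognition, collinearity grouping, and deterministic
  ordered labelling of detections against the frame geometry.
* **Registration and targeting** — `fitRigidTransform()` (SVD orthogonal
  Procrustes, det +1), `applyTransform()`, `buildAcpc()`,
  `targetCoordinates()` with the STN protocol window (|x| in [10, 13],
  y in [-2, -1], z in [-6, -2] mm relative to the AC–PC midpoint),
  `evaluateErrors()` for FLE / FRE / TRE reports.
* **Outcomes** — `improvementRate()` (`(pre - post)/pre x 100%`),
  `classifyOutcome()`, `tabulateOutcomes()`, `chiSquareTest()`,
  `pairedTTest()`, `summarizeCohort()`.

Central objects are S4 classes with validity checks and accessors
(`ImageSlice`, `EdgeMap`, `CircleAccumulator`, `FrameTemplate`,
`FiducialSet`, `FrameTransform`, `ACPCFrame`, ...). A thin command-line
wrapper ships at `exec/stereomark`
(`simulate | denoise | detect | match | register | target | outcomes`).

## A worked example

```r
library(stereomark)

## a 128x128 positioning slice: ring marker at (60.3, 70.7), radius 12 px,
## Gaussian noise sigma 15 on a 0-255 scale
spec <- phantomSpec(circles = data.frame(a = 60.3, b = 70.7, r = 12),
                    noiseSigma = 15, seed = 7)
ph  <- makePhantomSlice(spec)
den <- denoiseWavelet(ph$image)
detectCircles(den, rMin = 6, rMax = 18, k = 1)
#>    a  b  r votes     score aRefined bRefined rRefined
#> 1 60 71 14    62 0.8157895 60.27042 70.82692 12.70743
```

The coarse Hough bin (60, 71) is integer; the refined centre
(60.27, 70.83) recovers the fractional truth to under 0.15 px, and the
refined radius 12.7 sits within the ring's thickness of the nominal 12
(the coarse radius 14 is the marker's outer Canny edge ring — see the
vignette on why refinement, not the raw accumulator argmax, is the
detection output).

```r
coh <- makeOutcomeCohort(40, 40, c(37, 1, 2), c(35, 2, 3), seed = 7)
percentages(tabulateOutcomes(coh))
#>              cls
#> grp           markedlyEffective ineffective improved
#>   observation              92.5         2.5      5.0
#>   control                  87.5         5.0      7.5
ct <- chiSquareTest(tabulateOutcomes(coh))
#> Warning: expected count(s) below 5; the chi-square approximation may be poor
sprintf("chi-square %.3f, df %d, p = %.3f", ct$statistic, ct$df, ct$p.value)
#> [1] "chi-square 0.589, df 2, p = 0.745"

f <- buildAcpc(ac = c(0, 12, 0), pc = c(0, -12, 0), midsagittal = c(0, 0, 10))
targetCoordinates(f, "left", 11.5, -1.5, -4)
#> TargetCoordinate (left): AC-PC (-11.50, -1.50, -4.00) mm, within protocol
```

A cohort built from the category counts 37/1/2 and 35/2/3 (of 40 each)
tabulates to exactly 92.5/2.5/5.0% and 87.5/5.0/7.5%; the Pearson
chi-square of those six counts is 0.589 on 2 df. The left STN target at
(11.5, -1.5, -4) mm from the AC–PC midpoint lies inside the targeting
protocol window.

See `vignettes/stereotactic-mark-points.Rmd` for the models, parameter
choices, numerical decisions and limitations.

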