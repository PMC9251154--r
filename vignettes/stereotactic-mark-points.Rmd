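---
title: "Locating fiducial mark points and stereotactic targets with stereomark"
author: "stereomark authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating fiducial mark points and stereotactic targets with stereomark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereomark)
```

## The problem

Stereotactic neurosurgery for Parkinson's disease plans an electrode
trajectory to a deep-brain target (typically the subthalamic nucleus) from
a positioning MR scan acquired with a rigid frame on the patient's head.
The frame carries fiducial *mark points* — small bright markers and rods —
whose geometry is known exactly in frame coordinates. The computational
task is a pipeline: clean the image, find the mark points, decide which
physical marker each detection is, fit the rigid map from image space to
frame space, and express the surgical target in the AC–PC coordinate
system used for targeting. `stereomark` implements that pipeline end to
end, together with a synthetic phantom generator that provides exact
ground truth for every stage, and the pre/post UPDRS outcome statistics
used to evaluate the surgery.

Every stage is testable without any external data: the phantom generator
is first-class, deterministic (a spec plus a seed reproduces images
bit-for-bit), and records the true sub-pixel feature parameters it
rendered.

## Pixel and coordinate conventions

Images are matrices indexed `[row, col]`, 1-based, with pixel centres at
integer coordinates; a circle centre `(a, b)` is `(row, col)` in pixels.
Physical positions are `(row, col) * spacing` in mm. Lines use the normal
parameterization `a cos(theta) + b sin(theta) = rho` with `theta` in
`[0, pi)`, which has no vertical-line singularity; a pixel's image in the
line parameter space is one sinusoid, and the slope–intercept picture of
line detection is exactly this dual.

## Wavelet denoising

MR positioning slices are denoised by shrinkage in an orthonormal wavelet
basis. The family `psi_ab(t) = |a|^{-1/2} psi((t - b)/a)` (expansion
factor `a`, translation factor `b`) is realized discretely as a separable
two-dimensional DWT with Daubechies filters (default `db4`, i.e. 4
vanishing moments). Detail coefficients are soft-thresholded at the
universal threshold

\[ T = \hat\sigma \sqrt{2 \ln N}, \qquad
   \hat\sigma = \mathrm{median}(|HH_1|) / 0.6745, \]

with `N` the pixel count and `HH_1` the finest diagonal subband; the MAD
estimator makes `sigma_hat` insensitive to image structure. The threshold
scale, family, depth and soft/hard rule are all parameters
(`waveletParams()`), since no single choice suits every protocol.

Two numerical choices matter:

* **Periodic boundary extension.** The DWT is periodized, so
  decompose-plus-reconstruct is the identity to machine precision
  (`idwt2(dwt2(m))` agrees with `m` to ~1e-12 relative error; the test
  suite checks one level against an explicitly constructed orthogonal
  transform matrix). Symmetric extension would *not* be perfect
  reconstruction for orthogonal Daubechies filters. Image dimensions must
  be divisible by `2^levels`; positioning matrices (128, 256, 512) all
  are. Gradient computations elsewhere use replicate padding.
* **What denoising buys the pipeline.** On phantom slices the SNR against
  the noiseless render improves by about +1 dB at `sigma = 10`, +4 dB at
  20 and +8 dB at 40 (0–255 intensity scale). The universal threshold is
  deliberately conservative; its shrinkage bias grows with the total edge
  length in the image, so on a feature-dense slice at low noise
  (`sigma ~ 10`) the gain can reach zero. The practically important
  effect at heavy noise is edge-map *purity*: the Canny stage normalizes
  its thresholds to the maximum gradient, so the bright marker edges are
  found with or without denoising, but at `sigma = 50` a raw slice
  produces thousands of false edge pixels while a denoised one produces a
  few hundred — which is what keeps the Hough accumulator clean.

## Edge detection

`detectEdges()` is a Canny-style detector: Gaussian smoothing
(`sigma = 1.4` px default), Sobel gradients, non-maximum suppression along
the gradient direction quantized to 45 degrees, and hysteresis (seeds
above `high`, grown through 8-neighbours above `low`, both relative to the
maximum gradient magnitude, making the detector invariant to intensity
scaling). A ring marker of thickness `t` yields two concentric edge rings
near `r - t/2` and `r + t/2`; smoothing pushes the gradient extrema
slightly outward, which is why the ring-geometry test uses `sigma = 1`.

## Hough detection

**Lines.** Each edge pixel votes once per `theta` bin at the nearest
`rho` bin (defaults: 1 degree, 1 px). Peaks are extracted greedily with
non-maximum suppression; ties are broken by ascending `(theta, rho)`, so
peak lists are fully deterministic.

**Circles.** The accumulator is the three-dimensional array `A(a, b, r)`:
for each candidate radius, an edge pixel votes on the locus of centres at
that distance — its rasterized circle — so one pixel's votes across radii
form a cone in parameter space, and cones from pixels on a common circle
intersect at its parameters. Vote casting uses midpoint-circle
rasterization (first octant `db = round(sqrt(r^2 - da^2))`, reflected),
exact integer geometry that a brute-force triple loop reproduces
bin-for-bin — the test suite and acceptance checks do exactly that
comparison on 64x64 edge maps. Peaks are scored as votes divided by the
locus size for that radius, so large circles are not favoured merely for
having longer perimeters; suppression is 3-D Chebyshev with the same
deterministic tie rule, lexicographic on `(-score, a, b, r)`.

**Sub-pixel refinement.** The coarse Hough estimate is integer-binned,
and for ring markers its radius sits on an edge ring rather than the ring
centreline. `refineCenter()` therefore iterates two updates inside an
annular band around the current estimate: the centre moves to the
intensity-weighted centroid (weights are intensity above the band
minimum), and the radius moves to the gradient-magnitude-weighted mean
distance from the centre — standard sub-pixel edge localization, unbiased
for both annular and filled markers because the gradient profile is
symmetric about each edge. The radius is settled first: with the radius
still biased the band clips the marker's outer skirt asymmetrically and
would drag the centroid off-centre. Refined centres are clamped to 1.5 px
and radii to 2.5 px from the coarse bin. On noiseless phantoms the
refined centre lands within 0.05 px of fractional ground truth; across
the acceptance benchmark (100 slices, radii 6–20 px, noise up to
sigma 10) at least 95% of detections are within 1 px of the true centre
and 1 radius bin — the observed rate is 97–100% depending on the seed,
with mean centre error around 0.04 px.

## Matching detections to frame labels

A frame template (`frameTemplate()`) lists labelled marker positions in
mm, the anchor pair A–B, and optionally label sets expected to be
collinear (markers along one rod). Two operations implement the matching
flow:

* `groupCollinear()` finds maximal groups of 3+ detections whose
  perpendicular residual to the group's total-least-squares line is below
  a tolerance. Groups are seeded from every point pair and refined
  against the TLS fit; the suite cross-checks against exhaustive triple
  testing. Note that "collinear within a residual tolerance" is a
  property of the TLS geometry, not of visual intuition: three points
  spread far along one direction are nearly collinear almost regardless
  of their transverse scatter.
* `matchMarks()` labels detections. The anchor pair must be the
  template's unique maximum-separation pair (anything else is rejected,
  and near-ties within the tolerance are an explicit ambiguity error, not
  a guess). Every ordered detection pair is tried as (A, B): the
  two-point similarity transform pulls the detections back into template
  space, remaining labels are assigned one-to-one to nearest detections
  with deterministic tie-breaks on coordinates (never on input order),
  and the hypothesis with the smallest mean residual wins. Using the
  similarity (not rigid) transform here means the unknown image scale
  never enters; tolerances are in template mm. Matching is invariant to
  detection order and to rigid motions of the detections, verified
  property-style over random rotations; with 0.5 px jitter and a template
  whose markers are 10+ px apart, labelling is stable across seeds.

## Rigid registration and error metrics

`fitRigidTransform()` is SVD-based orthogonal Procrustes with the
determinant constrained to +1: rotation plus translation only, no
scaling, because a stereotactic frame is rigid and unscaled residuals
stay interpretable in mm. Collinear configurations are rejected as
rank-deficient. Noiseless recovery is exact to ~1e-14 mm; with isotropic
jitter of 0.2 mm per coordinate on the 8-point test template the mean
fiducial registration error over 50 replicates is ~0.25 mm, matching the
chi-distribution expectation for the residual degrees of freedom of a
2-D rigid fit.

`evaluateErrors()` reports the standard error decomposition against
phantom ground truth: FLE (per-mark detection error, mm), FRE (the
transform's RMS residual), and TRE (error propagated through the
transform to a target position). As expected from fiducial-error theory,
the TRE at the fiducial centroid is below the mean FLE.

## AC–PC targeting

`buildAcpc()` constructs the targeting frame: origin at the midpoint of
the anterior and posterior commissures, Y along PC→AC, Z orthogonal to Y
in the plane containing a midsagittal reference point, X = Y x Z
completing a right-handed frame, positive toward the patient's right.
The construction is invariant under global rigid motion of its three
defining points. `targetCoordinates()` places a target at signed offsets
from the origin (left-side targets carry negative x) and flags whether it
lies inside the protocol window for subthalamic targeting — |x| in
[10, 13] mm, y in [-2, -1] mm, z in [-6, -2] mm. Range boundaries are
treated as inclusive; the source ranges are written without open/closed
qualification, and inclusive is the convention that never rejects a
boundary plan.

## Outcome statistics

The clinical efficacy computations mirror the standard two-group pre/post
design: the improvement rate `(pre - post)/pre * 100`, a three-class
efficacy call (markedly effective at >=50% improvement, improved at
>=20%, else ineffective — the class boundaries are a convention of the
comparable clinical literature, configurable via
`efficacyThresholds()`), per-group tabulation with one-decimal
percentages, Pearson chi-square without continuity correction (small
expected counts warn rather than silently switching tests), and a
two-sided paired t-test. Feeding the reference category counts (37/1/2 of
40; 35/2/3 of 40) through `tabulateOutcomes()` reproduces
92.5/2.5/5.0% and 87.5/5.0/7.5% exactly. The Pearson statistic for that
table is 0.589 (df = 2, p = 0.74); a much larger chi-square value
sometimes quoted alongside such tables is not derivable from these six
counts by the Pearson formula, so the package always reports what it
computes. Under a simulated null the paired t-test's type-I rate at
alpha = 0.05 stays within [0.01, 0.10] over 1000 replicates.

## The phantom generator: what it emulates and what it does not

`phantomSpec()` + `makePhantomSlice()`/`makePhantomVolume()` emulate the
aspects of a positioning scan that the pipeline actually consumes: bright
ring (default) or disc markers with sub-pixel centres, bright rods, a
constant background with an optional smooth shading ramp, and additive
Gaussian (default) or Rician magnitude noise — MR magnitude images are
Rician, but at marker-level SNR the Gaussian approximation is standard.
Default study conditions: 128x128 px slices at 1 mm/px, marker radii
6–20 px, ring thickness 3 px, background 20,
marker amplitude 150, noise sigma up to 50 on a 0–255 scale. The cohort
generator draws improvement rates uniformly inside each efficacy band
with a 3-point margin so that rounding scores to integers can never cross
a class boundary, giving exact per-class counts by construction.

The phantoms deliberately do *not* model brain anatomy, bias fields,
pulse-sequence physics, partial-volume effects, or image distortion.
Passing tests therefore demonstrate the geometry and statistics of the
pipeline — detection accuracy, labelling stability, registration error
propagation — not robustness to anatomical clutter; on real scans the
edge thresholds, radius range and matching tolerance are the knobs to
revisit.

## Problem sizes and determinism

The test and acceptance workloads are sized for a desktop run: 100
detection slices at 128x128, 50–100 registration replicates, 20 seeds per
noise level for denoising, 1000 paired-t replicates. Every stochastic
stage takes an explicit integer seed, restores the caller's RNG state,
and is bit-reproducible for equal (spec, seed); every peak extraction and
assignment has a documented deterministic tie-break.

## Known limitations

* Circle detection assumes approximately circular, bright-on-dark
  markers; ellipse and parabola variants are out of scope.
* The 3-D accumulator is over `(a, b, r)` of in-plane circles; volumetric
  sphere detection is not implemented (volumes are processed per slice).
* `matchMarks()` is 2-D (slice geometry); 3-D correspondence comes from
  per-slice matches plus the rigid fit, which itself supports 2-D and
  3-D points.
* Templates with symmetric marker layouts (no unique longest pair, or
  near-ties) are rejected rather than guessed; such frames need a
  different anchor scheme.
* The denoiser's universal threshold is conservative at low noise; for
  `sigma < ~8` on feature-dense slices it can trade as much signal as it
  removes noise (use `thresholdScale < 1` there).

## A worked example

```{r example, eval = FALSE}
spec <- phantomSpec(circles = data.frame(a = 60.3, b = 70.7, r = 12),
                    lines = data.frame(theta = 0.6, rho = 45),
                    noiseSigma = 15, seed = 7)
ph <- makePhantomSlice(spec)
den <- denoiseWavelet(ph$image)
detectCircles(den, rMin = 6, rMax = 18, k = 1)

coh <- makeOutcomeCohort(40, 40, c(37, 1, 2), c(35, 2, 3), seed = 7)
tab <- tabulateOutcomes(coh)
percentages(tab)
chiSquareTest(tab)
```
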