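---
title: "Vertical phenotyping of rice from front-view images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertical phenotyping of rice from front-view images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertphen)
```

## The problem

Conventional shoot phenotyping summarises a plant with scalar traits --
height, tiller number, average leaf angle -- that ignore *where along the
stem* structure sits. Drought changes rice architecture vertically: panicle
emergence raises the plant's mass centre, water stress keeps lower leaves
alive and spread, rehydration compacts the canopy from the bottom up.
`vertphen` extracts two vertically-resolved descriptors from a single
front-view RGB image of a potted plant:

* **RHC**, the relative height of the plant centroid: the vertical distance
  from the silhouette's binary-moment centroid down to the plant bottom,
  divided by plant height. A dimensionless "growth focus" in (0, 1); 0.5 for
  a vertically uniform silhouette.
* **The vertical leaf-angle distribution** `A = a*ln(RH + 1) + b`, fitted to
  (angle, relative height) pairs of leaf line segments. `b` (degrees) is the
  basal leaf angle at RH = 0 because `ln(1) = 0`; `a` (degrees per ln-unit)
  sets how fast inclination rises with height -- the vertical heterogeneity
  of the canopy. RH enters the logarithm on the percent scale (0--100);
  using fractions would rescale both parameters and break comparability with
  the typical ranges `a` in 0--20 and `b` in -20--90 observed at most growth
  stages. Negative `a` is biologically meaningful late in heading, when the
  canopy compacts and upper leaves stop being the most erect, so the range
  check warns rather than errors.

Alongside these it computes the comparison descriptors **ALA** (mean
segment inclination), **GPAR** (fraction of plant pixels classified green --
a senescence indicator) and **PAR** (perimeter/area of the silhouette -- a
tiller-compactness index), and provides the downstream statistics used to
relate traits to growth status: one-way ANOVA with Tukey HSD across water
treatments, and multivariate linear regression of trait combinations
against measured responses such as above-ground dry matter (ADM) and the
canopy extinction coefficient K. Both responses are consumed from the trait
table; K is a radiometer-derived measurement and is never computed from
images.

## Processing chain

`analyzePlantImage()` runs: HSV segmentation, mask cleaning, silhouette
geometry, line-source extraction (skeleton by default, Canny edges as an
option), Hough leaf-segment detection, model fit, descriptors.

### Segmentation

Pixels are classified by an axis-aligned box in HSV space. Hue is handled
in degrees on a 0--360 circle; the default live-foliage box is hue 60--180
degrees, saturation >= 0.15, value >= 0.10. Hue wraparound across 0 degrees
is not supported -- green never straddles it; this is a documented
limitation, not a bug. Senescent material (yellow, hue near 55 degrees)
falls outside the default plant box; when senescing plants are analysed the
plant box should be widened (e.g. `hueLo = 40`) while the GPAR green box
stays strict (75--165 degrees) so that yellow organs count as plant but not
as green. Region-of-interest cropping is an explicit rectangle in the
configuration, matching manually framed pot shots, never automatic.

Cleaning removes 8-connected components smaller than 0.05% of the image
area and closes the mask with a 2-px disc: enough to suppress background
clutter without eroding 3-px-wide leaves. Connected-component labelling is
8-connected throughout, because rasterised diagonal strokes are only
8-connected and would otherwise fragment.

### Geometry and RHC

Plant extent uses the inverse-ECDF quantiles of the foreground row
distribution (`droopQuantile = 0.005` at each end, symmetric, 0 disables):
drooping leaf tips contribute a handful of pixels far below the canopy and
would otherwise inflate plant height. The same extent bounds the moment
sums, so the centroid, area and RHC are all computed over the droop-filtered
silhouette and `0 < RHC < 1` holds by construction. Heights are measured
upward from the bottom extent row; the raster's top-origin convention is
inverted exactly once, here.

The outer contour is the ordered 8-connected boundary chain of the largest
component; its arc length counts axis steps as 1 and diagonal steps as
sqrt(2). A single-pixel component has perimeter 1 by a documented degenerate
rule. PAR adds the boundaries of interior holes (tiller gaps carry the
compactness signal) and divides by silhouette area by default; a `hull`
denominator is available since some definitions normalise by the convex
hull.

### Leaf lines

The silhouette is reduced to line segments in three steps.

1. **Line source.** The default is a Zhang--Suen skeleton (1-px medial
   axis). Canny edges (Gaussian smoothing, Sobel gradients, quantized
   non-maximum suppression, hysteresis) are the alternative; because the
   input is a binary mask, whose true edge *is* the morphological boundary,
   the boundary is added as weak hysteresis support so each silhouette loop
   stays closed where quantized suppression breaks at corners, and the
   result is clipped to a 1-px dilation of the boundary.
2. **Culm suppression.** Dominant near-vertical lines (within 2 degrees of
   vertical, votes >= 0.4 x plant height) are erased from the line source
   before detection: a structure spanning most of the plant height at ~90
   degrees is stem, not leaf, and its junction remnants otherwise
   contaminate the angle samples. Erasure is skipped whenever the candidate
   would claim more than 30% of the raster, so a lone steep stroke -- a
   legitimate leaf -- is never deleted.
3. **Progressive Hough transform.** The full (theta, rho) accumulator
   (1 degree x 1 px resolution) is built over the remaining pixels; the
   strongest line is taken, its corridor pixels (within 1 px) are projected
   onto the line, split into runs at gaps > 5 px, and each run spanning at
   least 0.05 x plant height becomes a segment whose endpoints are the
   run's extreme pixels -- so reported angles are not quantized to the theta
   grid. Consumed pixels are removed and the loop repeats until the peak
   falls below 20 votes. Unlike the usual randomized progressive Hough this
   is fully deterministic, which makes reruns byte-identical and the whole
   pipeline testable to machine precision.

Two refinements follow. Accepted segments are *re-extended against the
cleaned mask*: thinning bends stroke bases where leaves join the stem, and
the accumulator's pixel consumption shortens strokes at crossings; scanning
the full mask corridor restores true endpoints and midpoints. Then
near-collinear duplicates (angle difference <= 5 degrees, mutual
midpoint-to-line distance <= 5 px) are merged into their longest-span
representative, and scene furniture is dropped: near-horizontal lines
longer than half the image width (pot rim, ground) and near-vertical lines
longer than 0.4 x plant height (culm remnants).

Each segment contributes one (angle, relative height) pair: the unsigned
inclination `atan(|dy|/|dx|)` folded into [0, 90] (left- and right-leaning
leaves are equivalent), and the midpoint height above the plant bottom as a
percent of plant height, clipped to [0, 100]. Merging is applied before the
fit by default, so a fragmented leaf contributes one pair; it can be
disabled.

### Model fit

Although the logarithmic model is commonly fitted with nonlinear least
squares, it is linear in (a, b) after `x = ln(RH + 1)`, so the package
solves the ordinary least squares problem on the transformed design -- the
exact minimiser of the same residual sum of squares, deterministic and
testable against the closed-form normal equations. At least 5 pairs are
required (two parameters plus meaningful residual degrees of freedom) and a
degenerate design (all heights equal) is refused. The reported `r` is the
Pearson correlation between fitted and observed angles, and RMSE is in
degrees. An optional length-weighted fit exists but is off: pairs are
weighted equally by default.

## The synthetic generator

`generatePlant()` renders a single plant on a uniform mid-grey background:
an optional vertical stem spanning the nominal plant height (300 px in a
400 x 400 canvas) and 16 straight leaf strokes (70 px long, 3 px wide)
alternating left/right. Leaf midpoint heights sit on a jittered stratified
grid over 5--100% of plant height -- rice leaves emerge at roughly regular
intervals along the culm (distichous phyllotaxy), and independent uniform
placement would stack several leaves at one height, producing overlapping
near-collinear strokes that no line detector could separate and defeating
the generator's purpose as an unambiguous reference. Each leaf's angle is
`a*ln(RH+1) + b` plus Gaussian noise (SD 2 degrees by default), folded into
[0, 90], and the stroke is rasterised at exactly that angle with no
anti-aliasing, so the truth record (per-leaf angle, midpoint, organ label;
foreground raster; RHC; ALA) is exact. Rendering is deterministic: the same
spec yields bit-identical images, and the caller's RNG stream is left
untouched.

What the generator does *not* emulate: curved blades (a `curvature` option
exists for stress testing but voids the truth-angle guarantee), panicles,
pots, soil, shadows, specular highlights, multiple tillers and
self-occlusion. Passing tests therefore demonstrate the correctness of the
geometric machinery under the stated stroke model, not photographic
robustness. Two mismatches between truth and measurement are intrinsic and
worth knowing: steep upper leaves overshoot the nominal stem top, so the
measured plant height slightly exceeds the nominal one and measured
relative heights compress by a few percent; and leaves hugging the culm at
more than ~85 degrees are geometrically close to stem and may be suppressed
with it.

`generateAngleSamples()` is the image-free counterpart: angles on a uniform
relative-height grid over [0, 100] with Gaussian noise, clipped to [0, 90],
for testing the fit in isolation.

## Statistics

`anovaTukey()` wraps `aov()` + `TukeyHSD()` at the 95% confidence level
with the star convention * p < 0.05, ** p < 0.01, *** p < 0.001. Synthetic
fixtures can have zero within-group variance, where the F ratio is
undefined; the limiting convention is reported (p = 1 when all group means
are equal, p = 0 otherwise) together with a `degenerate` flag. `mlrFit()`
is ordinary least squares with an intercept, reporting the Pearson
correlation of fitted versus measured response; exactly collinear columns
are dropped with a warning. `defaultFeatureSets()` exposes the standard
trait combinations for ADM (six sets) and K (three sets). Trait tables are
per-sample rows; pot-level aggregation, if wanted, is the caller's
`aggregate()` away.

## Numerical choices and validation design

* Quantile type 1 (inverse ECDF) for the droop filter: exactly reproducible
  from the row histogram.
* Ties in largest-component selection break to the lowest label;
  accumulator ties break to the lowest bin index -- determinism everywhere.
* The angle-recovery study draws one stroke per raster at every integer
  inclination 0--90 and requires the detected angle within 2 degrees; culm
  handling is off there because a bare-stroke scene has no culm.
* The image-free parameter-recovery study uses n = 200 samples, noise SD 3
  degrees, 100 seeds per parameter set, truths (5, 20), (10, 30), (15, 10);
  the scatter tolerance comes from the closed-form OLS sampling variance on
  the transformed design. End-to-end recovery renders 5 plants per truth
  and compares replicate-averaged fitted parameters at |da| <= 2,
  |db| <= 5. These problem sizes keep the full validation in well under a
  minute of compute while leaving the Monte Carlo error far below the
  tolerances.
* Per-stroke recovery (angle within 3 degrees, relative height within 3
  points, >= 80% of strokes) is validated on the generator defaults; denser
  canopies degrade recovery because stacked near-parallel strokes become
  mutually collinear -- a geometric ambiguity, not an implementation limit.

## Limitations

Single-plant scenes only; no occlusion handling, background modelling or
learned segmentation. Traits are in pixels and scale-free ratios -- RHC and
the angle model are deliberately invariant to camera distance, but PH in
centimetres requires external calibration. The Hough stage models leaves as
straight segments; strongly arched blades yield multiple segments whose
angles sample the local tangent, which is consistent with the model's use
of segment pairs but is not a per-leaf angle. Dates are analysed
separately; no repeated-measures correction is applied.
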