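#' @import methods
#' @importFrom stats coef predict
NULL

#' Binary plant mask
#'
#' An S4 container for the binary plant/background raster that underlies all
#' geometric trait extraction. Row 1 is the top of the image; a `TRUE` pixel
#' belongs to the plant. A mask with no foreground pixels is valid but
#' carries an explicit `empty` flag so downstream code can refuse it
#' gracefully instead of crashing.
#'
#' @slot mask logical matrix (H x W), `TRUE` = plant pixel.
#' @slot empty logical flag, `TRUE` iff the mask has no foreground pixel.
#'
#' @seealso [segmentPlant()], [cleanMask()], [plantGeometry()]
#' @export
setClass("PlantMask",
         slots = c(mask = "matrix", empty = "logical"))

setValidity("PlantMask", function(object) {
  m <- object@mask
  if (!is.logical(m)) return("mask must be a logical matrix")
  if (nrow(m) < 1 || ncol(m) < 1) return("mask must have positive dimensions")
  if (length(object@empty) != 1) return("empty must be a single flag")
  if (object@empty != !any(m)) return("empty flag inconsistent with mask content")
  TRUE
})

#' Construct a PlantMask
#'
#' @param mask logical (or coercible 0/1) matrix, `TRUE`/1 = plant.
#' @return A [PlantMask-class] object.
#' @export
PlantMask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  m <- matrix(as.logical(mask != 0), nrow(mask), ncol(mask))
  new("PlantMask", mask = m, empty = !any(m))
}

#' HSV colour-threshold box
#'
#' Bounds of the axis-aligned box in HSV space used to classify plant (or
#' green-organ) pixels. Hue is stored in degrees on a 0-360 circle (the
#' native 0-1 hue of [grDevices::rgb2hsv()] is multiplied by 360);
#' saturation and value are fractions in [0, 1]. The default box does not
#' support hue wraparound across 0 degrees -- green foliage never straddles
#' it.
#'
#' @slot hueLo,hueHi hue bounds, degrees, `hueLo < hueHi`.
#' @slot satLo minimum saturation fraction.
#' @slot valLo minimum value (brightness) fraction.
#' @export
setClass("HSVThresholds",
         slots = c(hueLo = "numeric", hueHi = "numeric",
                   satLo = "numeric", valLo = "numeric"))

setValidity("HSVThresholds", function(object) {
  if (object@hueLo < 0 || object@hueHi > 360) return("hue bounds outside [0, 360]")
  if (object@hueLo >= object@hueHi) return("hueLo must be < hueHi")
  if (object@satLo < 0 || object@satLo > 1) return("satLo outside [0, 1]")
  if (object@valLo < 0 || object@valLo > 1) return("valLo outside [0, 1]")
  TRUE
})

#' Construct HSV thresholds
#'
#' Defaults give a generous live-foliage box (hue 60-180 degrees,
#' saturation >= 0.15, value >= 0.10). For the stricter green-organ box used
#' by [greenFractionMask()] see [greenThresholds()].
#'
#' @param hueLo,hueHi hue bounds in degrees (0-360 scale).
#' @param satLo minimum saturation fraction.
#' @param valLo minimum value fraction.
#' @return An [HSVThresholds-class] object.
#' @export
hsvThresholds <- function(hueLo = 60, hueHi = 180, satLo = 0.15, valLo = 0.10) {
  new("HSVThresholds", hueLo = hueLo, hueHi = hueHi, satLo = satLo, valLo = valLo)
}

#' Strict green-organ thresholds
#'
#' A narrower hue box (75-165 degrees) that separates live green tissue from
#' senescent yellow organs (hue around 55 degrees); used as the default for
#' the GPAR green submask.
#'
#' @inheritParams hsvThresholds
#' @return An [HSVThresholds-class] object.
#' @export
greenThresholds <- function(hueLo = 75, hueHi = 165, satLo = 0.15, valLo = 0.10) {
  new("HSVThresholds", hueLo = hueLo, hueHi = hueHi, satLo = satLo, valLo = valLo)
}

#' Plant silhouette geometry
#'
#' Holds the geometric summary of one plant mask: the outer boundary chain
#' of the largest connected component, its convex hull, the droop-filtered
#' vertical extent, the image-moment centroid and the relative height of the
#' plant centroid (RHC). Heights are measured upward from `bottomRow` in
#' pixels; the raster's top-origin convention is inverted exactly once, in
#' this class's computations.
#'
#' @slot contour integer matrix (n x 2, columns x = image column,
#'   y = image row): ordered closed 8-connected outer boundary.
#' @slot hull matrix (h x 2): convex-hull vertices of the contour, consistent
#'   winding.
#' @slot topRow,bottomRow raster rows bounding the plant after droop
#'   filtering.
#' @slot plantHeightPx `bottomRow - topRow` (PH), pixels.
#' @slot centroid numeric (col, row): binary-moment centroid of foreground
#'   pixels within the droop-filtered extent.
#' @slot centroidHeightPx pixels from `bottomRow` up to the centroid.
#' @slot rhc centroid height / plant height, dimensionless in (0, 1).
#' @slot areaPx foreground pixel count within the extent.
#' @slot perimeterPx outer-contour arc length (8-connected metric, diagonal
#'   steps count sqrt(2)).
#' @slot holePerimeterPx summed arc length of interior hole boundaries of the
#'   largest component (tiller gaps); used by the PAR descriptor.
#' @seealso [plantGeometry()], [computeRHC()], [computePAR()]
#' @export
setClass("PlantGeometry",
         slots = c(contour = "matrix", hull = "matrix",
                   topRow = "numeric", bottomRow = "numeric",
                   plantHeightPx = "numeric",
                   centroid = "numeric", centroidHeightPx = "numeric",
                   rhc = "numeric", areaPx = "numeric",
                   perimeterPx = "numeric", holePerimeterPx = "numeric"))

setValidity("PlantGeometry", function(object) {
  if (object@plantHeightPx < 1) return("plant height must be >= 1 pixel")
  if (object@bottomRow - object@topRow != object@plantHeightPx)
    return("plantHeightPx must equal bottomRow - topRow")
  if (object@rhc <= 0 || object@rhc >= 1) return("rhc must lie in (0, 1)")
  if (object@areaPx <= 0) return("areaPx must be positive")
  if (length(object@centroid) != 2) return("centroid must be (col, row)")
  TRUE
})

#' Fitted vertical leaf-angle distribution
#'
#' Result of fitting the logarithmic model A = a*ln(RH + 1) + b relating
#' leaf inclination angle A (degrees from horizontal, 0-90) to relative leaf
#' height RH (percent of plant height, 0-100). `a` sets how fast angle
#' rises (or falls, when negative) with height; `b` is the basal angle at
#' RH = 0 since ln(1) = 0.
#'
#' @slot a curve-shape parameter, degrees per ln-unit.
#' @slot b intercept, degrees.
#' @slot nSegments number of (angle, height) pairs used.
#' @slot r Pearson correlation between fitted and observed angles.
#' @slot rmseDeg residual root-mean-square error, degrees.
#' @slot converged logical fit-success flag.
#' @seealso [fitAngleModel()], [predictAngle()], [validateFitRange()]
#' @export
setClass("AngleModelFit",
         slots = c(a = "numeric", b = "numeric", nSegments = "numeric",
                   r = "numeric", rmseDeg = "numeric", converged = "logical"))

setValidity("AngleModelFit", function(object) {
  if (object@rmseDeg < 0) return("rmseDeg must be >= 0")
  if (is.finite(object@r) && abs(object@r) > 1 + 1e-12) return("|r| must be <= 1")
  TRUE
})

#' One-way ANOVA plus Tukey HSD comparison of a trait across groups
#'
#' @slot trait trait name compared.
#' @slot fStatistic one-way ANOVA F statistic.
#' @slot pValue ANOVA p value.
#' @slot tukey data.frame of pairwise comparisons: `pair`, `diff`, `p_adj`,
#'   `stars`.
#' @slot stars significance stars for the overall test (`*` p < 0.05,
#'   `**` p < 0.01, `***` p < 0.001).
#' @slot degenerate `TRUE` when every group has zero internal variance and
#'   the limiting convention (p = 1 if all means equal, p = 0 otherwise) was
#'   applied.
#' @seealso [anovaTukey()]
#' @export
setClass("GroupComparison",
         slots = c(trait = "character", fStatistic = "numeric",
                   pValue = "numeric", tukey = "data.frame",
                   stars = "character", degenerate = "logical"))

setValidity("GroupComparison", function(object) {
  if (is.finite(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    return("pValue outside [0, 1]")
  TRUE
})

#' Multivariate linear regression of a growth response on trait features
#'
#' @slot features feature column names.
#' @slot coefficients named coefficients, intercept first.
#' @slot fitted fitted response values.
#' @slot response observed response values.
#' @slot pearsonR Pearson correlation of fitted vs observed response.
#' @seealso [mlrFit()]
#' @export
setClass("MLRResult",
         slots = c(features = "character", coefficients = "numeric",
                   fitted = "numeric", response = "numeric",
                   pearsonR = "numeric"))

setValidity("MLRResult", function(object) {
  if (length(object@coefficients) != length(object@features) + 1)
    return("coefficient count must be feature count + 1 (intercept)")
  if (is.finite(object@pearsonR) && abs(object@pearsonR) > 1 + 1e-12)
    return("|pearsonR| must be <= 1")
  TRUE
})

#' Specification of a synthetic rice plant image
#'
#' Parameters of the test-image generator: a single green (optionally partly
#' senescent-yellow) plant on a uniform mid-grey background, whose leaves
#' are straight strokes with inclination following A = a*ln(RH+1) + b plus
#' Gaussian angular noise. Because every stroke's angle, midpoint and pixel
#' set are known, the generator provides exact ground truth for every
#' pipeline stage.
#'
#' @slot aTrue,bTrue parameters of the vertical leaf-angle model.
#' @slot nLeaves number of leaf strokes.
#' @slot plantHeightPx nominal plant height (stem length), pixels.
#' @slot strokeWidthPx leaf/stem stroke thickness, pixels.
#' @slot leafLengthPx leaf stroke length, pixels.
#' @slot angleNoiseSdDeg SD of Gaussian angular noise, degrees.
#' @slot greenFraction expected fraction of leaves rendered green (the rest
#'   senescent yellow, hue ~ 55 degrees).
#' @slot stem draw a vertical stem stroke spanning the plant height.
#' @slot canvas image size c(H, W), pixels.
#' @slot seed RNG seed making the render reproducible.
#' @slot curvature leaf bowing, pixels of sagitta; nonzero values are for
#'   stress testing only and void the straight-line truth-angle guarantee.
#' @slot texturedBackground add faint grey background speckle (exercises
#'   mask cleaning); speckle stays outside every green/yellow HSV box.
#' @seealso [syntheticPlantSpec()], [generatePlant()]
#' @export
setClass("SyntheticPlantSpec",
         slots = c(aTrue = "numeric", bTrue = "numeric", nLeaves = "numeric",
                   plantHeightPx = "numeric", strokeWidthPx = "numeric",
                   leafLengthPx = "numeric", angleNoiseSdDeg = "numeric",
                   greenFraction = "numeric", stem = "logical",
                   canvas = "numeric", seed = "numeric",
                   curvature = "numeric", texturedBackground = "logical"))

setValidity("SyntheticPlantSpec", function(object) {
  if (object@nLeaves < 1) return("nLeaves must be >= 1")
  if (length(object@canvas) != 2) return("canvas must be c(H, W)")
  if (object@plantHeightPx > object@canvas[1])
    return("plantHeightPx exceeds canvas height")
  if (object@greenFraction < 0 || object@greenFraction > 1)
    return("greenFraction outside [0, 1]")
  if (object@strokeWidthPx < 1) return("strokeWidthPx must be >= 1")
  if (object@angleNoiseSdDeg < 0) return("angleNoiseSdDeg must be >= 0")
  TRUE
})

#' Ground truth of a synthetic plant render
#'
#' @slot leaves data.frame, one row per leaf: `rel_height` (percent, midpoint
#'   height over nominal plant height), `angle_deg` (rendered stroke angle,
#'   0-90), `mid_x`, `mid_y` (midpoint raster coordinates), `green` (logical
#'   organ label).
#' @slot raster logical foreground matrix (every painted plant pixel).
#' @slot labels integer matrix: 0 background, 1 green organ, 2 yellow organ.
#' @slot trueRhc relative centroid height recomputed from the raster by
#'   direct pixel-mean (the geometry oracle).
#' @slot truePhPx raster extent span (no droop filtering), pixels.
#' @slot trueAlaDeg mean rendered leaf angle, degrees.
#' @slot groundRow raster row of the plant base.
#' @export
setClass("SyntheticTruth",
         slots = c(leaves = "data.frame", raster = "matrix", labels = "matrix",
                   trueRhc = "numeric", truePhPx = "numeric",
                   trueAlaDeg = "numeric", groundRow = "numeric"))

setValidity("SyntheticTruth", function(object) {
  if (nrow(object@leaves) > 0 &&
      (any(object@leaves$rel_height < 0) || any(object@leaves$rel_height > 100)))
    return("per-leaf rel_height outside [0, 100]")
  if (object@trueRhc <= 0 || object@trueRhc >= 1) return("trueRhc outside (0, 1)")
  TRUE
})
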