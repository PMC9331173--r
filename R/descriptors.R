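# Comparison shape descriptors GPAR and PAR.

#' Greenness projected plant area ratio (GPAR)
#'
#' The fraction of plant silhouette pixels classified as green organ:
#' |green| / |plant|. A within-plant ratio (projected plant pixels, not
#' whole-image pixels); it falls as organs senesce to yellow. Invariant
#' under any rigid transform applied to both masks.
#'
#' @param greenMask green-organ [PlantMask-class]
#'   (see [greenFractionMask()]); must be a subset of `plantMask`.
#' @param plantMask nonempty plant [PlantMask-class].
#' @return fraction in [0, 1].
#' @export
computeGPAR <- function(greenMask, plantMask) {
  stopifnot(is(greenMask, "PlantMask"), is(plantMask, "PlantMask"))
  if (isEmptyMask(plantMask)) stop("empty plant mask: GPAR undefined")
  g <- maskMatrix(greenMask); p <- maskMatrix(plantMask)
  if (!identical(dim(g), dim(p))) stop("mask dimensions differ")
  if (any(g & !p)) stop("green mask is not a subset of the plant mask")
  sum(g) / sum(p)
}

#' Perimeter-area ratio (PAR) of the plant silhouette
#'
#' Compactness index of the tillers: total boundary length divided by area.
#' The perimeter is the outer contour of the largest connected component
#' plus its interior hole boundaries (tiller gaps carry the compactness
#' signal), measured with the 8-connected arc-length metric (diagonal steps
#' sqrt(2)). The denominator is the silhouette area by default; `"hull"`
#' uses the convex-hull area instead.
#'
#' @param geometry a [PlantGeometry-class].
#' @param denominator `"mask"` (silhouette pixel count, default) or
#'   `"hull"` (convex-hull polygon area).
#' @return PAR in 1/pixels, positive for any nonempty mask.
#' @export
computePAR <- function(geometry, denominator = c("mask", "hull")) {
  stopifnot(is(geometry, "PlantGeometry"))
  denominator <- match.arg(denominator)
  per <- geometry@perimeterPx + geometry@holePerimeterPx
  area <- if (denominator == "mask") geometry@areaPx else polygonArea(geometry@hull)
  if (area <= 0) stop("zero area: PAR undefined")
  per / area
}

# Shoelace area of a polygon given as vertex matrix (x, y).
polygonArea <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' All shape descriptors of one image
#'
#' Convenience wrapper computing GPAR and PAR together with the pixel
#' measures they derive from.
#'
#' @param image H x W x 3 source image.
#' @param plantMask the cleaned plant [PlantMask-class].
#' @param geometry its [PlantGeometry-class].
#' @param greenBox strict green [HSVThresholds-class], default
#'   [greenThresholds()].
#' @param parDenominator passed to [computePAR()].
#' @return list: `gpar`, `par`, `area_px`, `green_area_px`, `perimeter_px`.
#' @export
shapeDescriptors <- function(image, plantMask, geometry,
                             greenBox = greenThresholds(),
                             parDenominator = "mask") {
  green <- greenFractionMask(image, plantMask, greenBox)
  list(gpar = computeGPAR(green, plantMask),
       par = computePAR(geometry, parDenominator),
       area_px = geometry@areaPx,
       green_area_px = sum(maskMatrix(green)),
       perimeter_px = geometry@perimeterPx + geometry@holePerimeterPx)
}
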