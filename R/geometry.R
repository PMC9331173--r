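# Silhouette geometry: contour, hull, extent, centroid, RHC.

#' Extract the outer contour of the plant silhouette
#'
#' Returns the ordered closed boundary chain (8-connected) of the largest
#' connected component of the mask, as an n x 2 matrix with columns `x`
#' (image column) and `y` (image row). A single-pixel component yields a
#' one-point contour whose perimeter is defined as 1 (degenerate rule).
#'
#' @param mask a [PlantMask-class]; must be nonempty.
#' @return integer matrix (n x 2), columns `x`, `y`.
#' @export
extractContour <- function(mask) {
  stopifnot(is(mask, "PlantMask"))
  if (isEmptyMask(mask)) stop("cannot extract a contour from an empty mask")
  comp <- largestComponent(maskMatrix(mask))
  oc <- EBImage::ocontour(matrix(as.numeric(comp), nrow(comp), ncol(comp)))[[1]]
  # ocontour is 0-based in (dim1, dim2) = (row, col) order for a plain matrix
  pts <- cbind(x = oc[, 2] + 1L, y = oc[, 1] + 1L)
  storage.mode(pts) <- "integer"
  pts
}

#' Convex hull of contour points
#'
#' Minimal convex polygon containing every point, via Andrew/Graham scan
#' ([grDevices::chull()]). Vertices are returned in consistent winding order
#' (clockwise in raster coordinates with y pointing down). Collinear input
#' degenerates to its two extreme points.
#'
#' @param points n x 2 matrix of (x, y) points, n >= 1.
#' @return matrix of hull vertices (h x 2).
#' @export
convexHullPolygon <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1) stop("need at least one point")
  idx <- grDevices::chull(points[, 1], points[, 2])
  points[idx, , drop = FALSE]
}

#' Droop-filtered vertical extent of the plant
#'
#' The top and bottom rows of the plant are taken as the `droopQuantile` and
#' `1 - droopQuantile` quantiles of the foreground row distribution
#' (inverse-ECDF, quantile type 1), so that sparse drooping leaf-tip pixels
#' beyond either extreme are excluded from the plant height. `droopQuantile
#' = 0` disables filtering and returns the min/max foreground rows.
#'
#' @param mask a nonempty [PlantMask-class].
#' @param droopQuantile fraction in [0, 0.5) trimmed at each extreme;
#'   default 0.005.
#' @return list with `topRow`, `bottomRow`, `plantHeightPx`.
#' @export
plantExtent <- function(mask, droopQuantile = 0.005) {
  stopifnot(is(mask, "PlantMask"))
  if (isEmptyMask(mask)) stop("empty mask has no extent")
  if (droopQuantile < 0 || droopQuantile >= 0.5)
    stop("droopQuantile must lie in [0, 0.5)")
  rows <- rowIndexMat(maskMatrix(mask))[maskMatrix(mask)]
  top <- as.numeric(stats::quantile(rows, droopQuantile, type = 1))
  bottom <- as.numeric(stats::quantile(rows, 1 - droopQuantile, type = 1))
  if (bottom <= top) stop("plant height undefined: mask spans a single row")
  list(topRow = top, bottomRow = bottom, plantHeightPx = bottom - top)
}

#' Binary-moment centroid of a mask
#'
#' The zeroth/first image moments of the binary silhouette: the arithmetic
#' mean of foreground pixel coordinates (M10/M00, M01/M00). All mask pixels
#' are weighted equally (no intensity weighting).
#'
#' @param mask a nonempty [PlantMask-class].
#' @return numeric `c(col, row)`.
#' @export
computeCentroid <- function(mask) {
  stopifnot(is(mask, "PlantMask"))
  if (isEmptyMask(mask)) stop("empty mask has no centroid")
  m <- maskMatrix(mask)
  c(mean(colIndexMat(m)[m]), mean(rowIndexMat(m)[m]))
}

#' Relative height of the plant centroid (RHC)
#'
#' RHC = centroid height / plant height: the vertical distance from the
#' silhouette centroid down to the plant bottom, as a fraction of the
#' droop-filtered plant height. Foreground pixels outside the extent rows
#' (filtered droop) are excluded from the moment sum, so RHC always lies in
#' (0, 1) for a mask spanning at least two rows.
#'
#' @param mask a nonempty [PlantMask-class].
#' @param extent output of [plantExtent()] (or list with `topRow`,
#'   `bottomRow`).
#' @return RHC fraction in (0, 1).
#' @examples
#' m <- matrix(FALSE, 20, 10); m[6:15, ] <- TRUE
#' computeRHC(PlantMask(m), plantExtent(PlantMask(m), 0))   # 0.5
#' @export
computeRHC <- function(mask, extent) {
  stopifnot(is(mask, "PlantMask"))
  if (isEmptyMask(mask)) stop("empty mask has no centroid")
  top <- extent$topRow; bottom <- extent$bottomRow
  if (bottom - top < 1) stop("zero plant height")
  m <- maskMatrix(mask)
  rows <- rowIndexMat(m)[m]
  rows <- rows[rows >= top & rows <= bottom]
  if (length(rows) == 0) stop("no foreground pixels within the extent")
  (bottom - mean(rows)) / (bottom - top)
}

# Summed arc length of interior hole boundaries of a component mask.
holePerimeter <- function(comp) {
  filled <- EBImage::fillHull(matrix(as.numeric(comp), nrow(comp), ncol(comp))) > 0.5
  holes <- filled & !comp
  if (!any(holes)) return(0)
  lab <- label8(holes)
  ocs <- EBImage::ocontour(matrix(as.numeric(lab), nrow(lab), ncol(lab)))
  sum(vapply(ocs, function(p) chainArcLength(p), numeric(1)))
}

#' Full geometric summary of a plant mask
#'
#' Runs [extractContour()], [convexHullPolygon()], [plantExtent()],
#' [computeCentroid()] (restricted to the droop-filtered extent) and
#' [computeRHC()], and measures area, outer perimeter and interior hole
#' perimeter of the largest connected component.
#'
#' @param mask a nonempty [PlantMask-class] spanning at least two rows.
#' @param droopQuantile see [plantExtent()].
#' @return A [PlantGeometry-class] object.
#' @export
plantGeometry <- function(mask, droopQuantile = 0.005) {
  stopifnot(is(mask, "PlantMask"))
  if (isEmptyMask(mask)) stop("cannot compute geometry of an empty mask")
  ext <- plantExtent(mask, droopQuantile)
  m <- maskMatrix(mask)
  inExtent <- m & rowIndexMat(m) >= ext$topRow & rowIndexMat(m) <= ext$bottomRow
  cx <- mean(colIndexMat(m)[inExtent])
  cy <- mean(rowIndexMat(m)[inExtent])
  contour <- extractContour(mask)
  hull <- convexHullPolygon(contour)
  comp <- largestComponent(m)
  new("PlantGeometry",
      contour = contour, hull = hull,
      topRow = ext$topRow, bottomRow = ext$bottomRow,
      plantHeightPx = ext$plantHeightPx,
      centroid = c(cx, cy),
      centroidHeightPx = ext$bottomRow - cy,
      rhc = (ext$bottomRow - cy) / ext$plantHeightPx,
      areaPx = sum(inExtent),
      perimeterPx = chainArcLength(contour),
      holePerimeterPx = holePerimeter(comp))
}
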