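# Plant/background segmentation by HSV colour thresholding.

#' Read a front-view plant image
#'
#' Reads a PNG or JPEG image into an H x W x 3 numeric array in [0, 1] with
#' row 1 at the top of the image (channel order R, G, B).
#'
#' @param path image file path.
#' @return numeric array, H x W x 3.
#' @export
readPlantImage <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2) d <- array(rep(d, 3), c(dim(d), 3))
  if (dim(d)[3] > 3) d <- d[, , 1:3, drop = FALSE]
  # EBImage stores (x = column, y = row); transpose to row-major H x W x 3
  aperm(d, c(2, 1, 3))
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground is written as 255, background as 0.
#'
#' @param mask a [PlantMask-class] or logical matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  m <- if (is(mask, "PlantMask")) maskMatrix(mask) else mask
  png::writePNG(matrix(as.numeric(m != 0), nrow(m), ncol(m)), path)
  invisible(path)
}

#' Segment the plant from the background
#'
#' Classifies every pixel by whether its HSV triple falls inside the
#' threshold box (hue within `[hueLo, hueHi]`, saturation >= `satLo`, value
#' >= `valLo`). The result is deterministic for fixed inputs. If no pixel
#' qualifies, an empty mask is returned with a warning rather than an error,
#' so batch runs can log and continue.
#'
#' @param image H x W x 3 numeric array in [0, 1] (see [readPlantImage()]).
#' @param thresholds an [HSVThresholds-class] box; default [hsvThresholds()].
#' @param roi optional region-of-interest crop `c(top, bottom, left, right)`
#'   in raster rows/columns; pixels outside it are treated as background.
#' @return A [PlantMask-class] with dimensions of `image`.
#' @examples
#' img <- array(0, c(4, 4, 3)); img[, , 2] <- 1   # pure green
#' sum(maskMatrix(segmentPlant(img)))             # 16
#' @export
segmentPlant <- function(image, thresholds = hsvThresholds(), roi = NULL) {
  if (!is.array(image) || length(dim(image)) != 3 || any(dim(image)[1:2] < 1))
    stop("image must be a nonempty H x W x 3 array")
  stopifnot(is(thresholds, "HSVThresholds"))
  hsv <- rgbArrayToHsv(image)
  inbox <- hsv$h >= thresholds@hueLo & hsv$h <= thresholds@hueHi &
    hsv$s >= thresholds@satLo & hsv$v >= thresholds@valLo
  m <- matrix(inbox, hsv$dim[1], hsv$dim[2])
  if (!is.null(roi)) {
    stopifnot(length(roi) == 4)
    keep <- matrix(FALSE, nrow(m), ncol(m))
    keep[max(1, roi[1]):min(nrow(m), roi[2]),
         max(1, roi[3]):min(ncol(m), roi[4])] <- TRUE
    m <- m & keep
  }
  if (!any(m)) warning("segmentation produced an empty mask")
  PlantMask(m)
}

#' Denoise a plant mask
#'
#' Removes 8-connected components smaller than `minComponentArea` pixels,
#' then applies morphological closing with a disc of the given radius to
#' bridge small gaps in thin leaves. With both parameters zero this is the
#' identity. The output never extends beyond the closing-dilation envelope
#' of the input.
#'
#' @param mask a [PlantMask-class].
#' @param minComponentArea components with fewer pixels are dropped;
#'   `NULL` uses the default 0.05\% of the image area.
#' @param closingRadius disc radius in pixels for morphological closing
#'   (0 = none).
#' @return A cleaned [PlantMask-class].
#' @export
cleanMask <- function(mask, minComponentArea = NULL, closingRadius = 2) {
  stopifnot(is(mask, "PlantMask"))
  m <- maskMatrix(mask)
  if (is.null(minComponentArea))
    minComponentArea <- ceiling(0.0005 * length(m))
  if (!any(m)) return(PlantMask(m))
  if (minComponentArea > 0) {
    lab <- label8(m)
    ar <- componentAreas(lab)
    keep <- which(ar >= minComponentArea)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  if (closingRadius > 0 && any(m)) {
    brush <- EBImage::makeBrush(2 * closingRadius + 1, shape = "disc")
    m <- EBImage::closing(matrix(as.numeric(m), nrow(m), ncol(m)), brush) > 0.5
  }
  PlantMask(m)
}

#' Green-organ submask for GPAR
#'
#' Returns the subset of plant-mask pixels whose colour falls in a stricter
#' green hue box, separating live green tissue from senescent yellow organs.
#' Always a subset of `mask`.
#'
#' @param image the H x W x 3 source image.
#' @param mask the plant [PlantMask-class] (same dimensions as `image`).
#' @param thresholds strict green box, default [greenThresholds()].
#' @return A [PlantMask-class] marking green plant pixels.
#' @seealso [computeGPAR()]
#' @export
greenFractionMask <- function(image, mask, thresholds = greenThresholds()) {
  stopifnot(is(mask, "PlantMask"))
  if (!is.array(image) || !identical(dim(image)[1:2], dim(mask)))
    stop("image and mask dimensions differ")
  green <- suppressWarnings(segmentPlant(image, thresholds))
  PlantMask(maskMatrix(green) & maskMatrix(mask))
}
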