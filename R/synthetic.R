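# Synthetic rice-like plant renders with exact ground truth.

#' Construct a synthetic plant specification
#'
#' Defaults describe a rice-like potted subject at desk scale: 16 leaves on
#' a 300-px plant in a 400 x 400 canvas, 3-px strokes, leaf angles following
#' A = a*ln(RH+1) + b with 2 degrees of angular noise, all foliage green.
#' Leaf midpoints are placed on a jittered stratified grid over 5-100
#' percent of plant height, emulating the regular (distichous) leaf
#' arrangement along a rice culm.
#'
#' @param aTrue,bTrue vertical leaf-angle model parameters.
#' @param nLeaves number of leaf strokes.
#' @param plantHeightPx nominal plant (stem) height, pixels.
#' @param strokeWidthPx stroke thickness, pixels.
#' @param leafLengthPx leaf stroke length, pixels.
#' @param angleNoiseSdDeg SD of Gaussian angular noise, degrees.
#' @param greenFraction fraction of leaves rendered green (rest senescent
#'   yellow).
#' @param stem draw the vertical stem.
#' @param canvas image dimensions c(H, W).
#' @param seed RNG seed.
#' @param curvature leaf bowing sagitta in pixels (stress-testing only; no
#'   truth-angle guarantee when nonzero).
#' @param texturedBackground sprinkle faint desaturated-green speckle that
#'   passes segmentation and must be removed by [cleanMask()].
#' @return A [SyntheticPlantSpec-class].
#' @export
syntheticPlantSpec <- function(aTrue = 10, bTrue = 30, nLeaves = 16,
                               plantHeightPx = 300, strokeWidthPx = 3,
                               leafLengthPx = 70, angleNoiseSdDeg = 2,
                               greenFraction = 1, stem = TRUE,
                               canvas = c(400, 400), seed = 1,
                               curvature = 0, texturedBackground = FALSE) {
  new("SyntheticPlantSpec", aTrue = aTrue, bTrue = bTrue, nLeaves = nLeaves,
      plantHeightPx = plantHeightPx, strokeWidthPx = strokeWidthPx,
      leafLengthPx = leafLengthPx, angleNoiseSdDeg = angleNoiseSdDeg,
      greenFraction = greenFraction, stem = stem, canvas = canvas,
      seed = seed, curvature = curvature,
      texturedBackground = texturedBackground)
}

# Fold an angle in degrees into [0, 90] (unsigned inclination).
foldAngle <- function(x) {
  x <- abs(x) %% 180
  ifelse(x > 90, 180 - x, x)
}

# Paint a thick straight stroke (capsule of radius width/2) into labels.
paintStroke <- function(labels, p1, p2, width, value) {
  h <- nrow(labels); w <- ncol(labels)
  r <- width / 2
  rr <- max(1L, floor(min(p1[2], p2[2]) - r)):min(h, ceiling(max(p1[2], p2[2]) + r))
  cc <- max(1L, floor(min(p1[1], p2[1]) - r)):min(w, ceiling(max(p1[1], p2[1]) + r))
  py <- matrix(rr, length(rr), length(cc))
  px <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
  l2 <- dx^2 + dy^2
  t <- if (l2 == 0) 0 else pmin(1, pmax(0, ((px - p1[1]) * dx + (py - p1[2]) * dy) / l2))
  d2 <- (px - (p1[1] + t * dx))^2 + (py - (p1[2] + t * dy))^2
  hit <- d2 <= r^2
  labels[rr, cc][hit] <- value
  labels
}

paintLeaf <- function(labels, p1, p2, width, value, curvature) {
  if (curvature == 0) return(paintStroke(labels, p1, p2, width, value))
  # quadratic bezier with perpendicular control offset = 2 * sagitta
  mid <- (p1 + p2) / 2
  d <- p2 - p1; nl <- sqrt(sum(d^2))
  nrm <- c(-d[2], d[1]) / nl
  ctrl <- mid + 2 * curvature * nrm
  ts <- seq(0, 1, length.out = 21)
  pts <- t(vapply(ts, function(t)
    (1 - t)^2 * p1 + 2 * t * (1 - t) * ctrl + t^2 * p2, numeric(2)))
  for (k in seq_len(nrow(pts) - 1L))
    labels <- paintStroke(labels, pts[k, ], pts[k + 1L, ], width, value)
  labels
}

#' Generate a synthetic plant image with ground truth
#'
#' Renders a single plant on a uniform mid-grey background: an optional
#' vertical stem spanning the nominal plant height and `nLeaves` straight
#' leaf strokes alternating left/right. Leaf midpoint relative heights are
#' drawn uniformly over [5, 100] percent; each leaf's inclination is
#' a*ln(RH+1) + b plus Gaussian noise, folded into [0, 90], and the stroke
#' is rendered at exactly that angle. Rendering is deterministic for a
#' fixed spec (identical spec => bit-identical image).
#'
#' @param spec a [SyntheticPlantSpec-class].
#' @return list with `image` (H x W x 3 array in [0, 1]) and `truth`
#'   (a [SyntheticTruth-class]).
#' @export
generatePlant <- function(spec) {
  stopifnot(is(spec, "SyntheticPlantSpec"))
  H <- spec@canvas[1]; W <- spec@canvas[2]
  PH <- spec@plantHeightPx
  Lf <- spec@leafLengthPx
  wd <- spec@strokeWidthPx
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(spec@seed)

  groundRow <- H - max(4, floor((H - PH) / 2))
  topRow <- groundRow - PH
  cx <- round(W / 2)
  n <- spec@nLeaves
  # jittered stratified heights over [5, 100]: rice leaves emerge at roughly
  # regular intervals along the culm (distichous phyllotaxy), so midpoints
  # are spread rather than i.i.d.-clumped
  edges <- seq(5, 100, length.out = n + 1L)
  rh <- edges[-(n + 1L)] + stats::runif(n) * diff(edges)
  ang <- foldAngle(spec@aTrue * log(rh + 1) + spec@bTrue +
                     stats::rnorm(n, 0, spec@angleNoiseSdDeg))
  side <- rep(c(1, -1), length.out = n)
  green <- stats::runif(n) < spec@greenFraction
  arad <- ang * pi / 180
  midRow <- groundRow - rh / 100 * PH
  midCol <- cx + (Lf / 2) * side * cos(arad)
  p1x <- midCol - (Lf / 2) * side * cos(arad)   # stem-side (lower) endpoint
  p1y <- midRow + (Lf / 2) * sin(arad)
  p2x <- midCol + (Lf / 2) * side * cos(arad)
  p2y <- midRow - (Lf / 2) * sin(arad)
  margin <- wd / 2 + 1
  if (topRow < margin || groundRow > H - 1 ||
      any(p2y < margin) || any(p1y > H - margin) ||
      any(c(p1x, p2x) < margin) || any(c(p1x, p2x) > W - margin))
    stop("synthetic spec cannot fit the canvas; enlarge canvas or shorten leaves")

  labels <- matrix(0L, H, W)
  if (spec@stem)
    labels <- paintStroke(labels, c(cx, groundRow), c(cx, topRow), wd, 1L)
  for (i in seq_len(n))
    labels <- paintLeaf(labels, c(p1x[i], p1y[i]), c(p2x[i], p2y[i]), wd,
                        if (green[i]) 1L else 2L, spec@curvature)

  img <- array(0.5, c(H, W, 3))
  if (spec@texturedBackground) {
    ns <- 40L
    sr <- sample.int(H, ns, replace = TRUE)
    sc <- sample.int(W, ns, replace = TRUE)
    for (k in seq_len(ns)) {
      rr <- sr[k]:min(H, sr[k] + sample.int(2, 1) - 1L)
      cc <- sc[k]:min(W, sc[k] + sample.int(2, 1) - 1L)
      bg <- labels[rr, cc] == 0L
      # desaturated green speckle: hsv(120, 0.2, 0.4)
      img[, , 1][rr, cc][bg] <- 0.32
      img[, , 2][rr, cc][bg] <- 0.40
      img[, , 3][rr, cc][bg] <- 0.32
    }
  }
  greenRGB <- c(0.25, 0.72, 0.30)    # hue ~ 126 deg
  yellowRGB <- c(0.90, 0.83, 0.10)   # hue ~ 55 deg (senescent)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[labels == 1L] <- greenRGB[ch]
    plane[labels == 2L] <- yellowRGB[ch]
    img[, , ch] <- plane
  }

  raster <- labels > 0L
  rows <- rowIndexMat(raster)[raster]
  bot <- max(rows); top <- min(rows)
  truth <- new("SyntheticTruth",
               leaves = data.frame(rel_height = rh, angle_deg = ang,
                                   mid_x = midCol, mid_y = midRow,
                                   green = green),
               raster = raster, labels = labels,
               trueRhc = (bot - mean(rows)) / (bot - top),
               truePhPx = bot - top,
               trueAlaDeg = mean(ang),
               groundRow = groundRow)
  list(image = img, truth = truth)
}

#' Generate image-free (angle, relative height) samples
#'
#' Samples on a uniform relative-height grid over [0, 100] with Gaussian
#' angular noise, clipped to [0, 90]; the image-free fixture for testing the
#' model fit in isolation.
#'
#' @param aTrue,bTrue model parameters.
#' @param n sample count.
#' @param noiseSd Gaussian angle noise SD, degrees.
#' @param seed RNG seed.
#' @return data.frame with `rel_height`, `angle_deg`.
#' @export
generateAngleSamples <- function(aTrue, bTrue, n, noiseSd = 0, seed = 1) {
  stopifnot(n >= 1)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(seed)
  rh <- seq(0, 100, length.out = n)
  ang <- aTrue * log(rh + 1) + bTrue + stats::rnorm(n, 0, noiseSd)
  data.frame(rel_height = rh, angle_deg = pmin(90, pmax(0, ang)))
}
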