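# Reduction of the silhouette to leaf line segments: edge detection,
# skeletonization and a deterministic progressive Hough transform.

#' Canny edge detection on a plant mask
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and double-threshold hysteresis (weak edge
#' pixels survive only in components containing a strong pixel). Thresholds
#' are fractions of the maximum gradient magnitude. The result is clipped to
#' a 1-px dilation of the mask's morphological boundary, so edges always
#' trace the silhouette.
#'
#' @param mask a nonempty [PlantMask-class].
#' @param lowThr,highThr hysteresis thresholds as fractions of the maximum
#'   gradient magnitude.
#' @param sigma Gaussian smoothing SD in pixels.
#' @return logical edge matrix, same dimensions as the mask.
#' @export
detectEdges <- function(mask, lowThr = 0.1, highThr = 0.3, sigma = 1) {
  stopifnot(is(mask, "PlantMask"))
  if (isEmptyMask(mask)) stop("cannot detect edges in an empty mask")
  mm0 <- maskMatrix(mask)
  m <- matrix(as.numeric(mm0), nrow(mm0), ncol(mm0))
  sm <- gaussianSmooth(m, sigma)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gy <- convolve2(sm, kx)            # gradient across rows (vertical)
  gx <- convolve2(sm, t(kx))         # gradient across columns (horizontal)
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nrow(m), ncol(m)))
  mag <- mag / max(mag)
  # quantize gradient direction into 4 sectors and suppress non-maxima
  ang <- atan2(gy, gx)
  sector <- floor(((ang + pi) / (pi / 4)) %% 4 + 0.5) %% 4
  keep <- matrix(FALSE, nrow(m), ncol(m))
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (s in 0:3) {
    d <- offs[[as.character(s)]]
    n1 <- shiftMat(mag, d[1], d[2])
    n2 <- shiftMat(mag, -d[1], -d[2])
    keep <- keep | (sector == s & mag >= n1 & mag >= n2)
  }
  mm <- maskMatrix(mask)
  er <- EBImage::erode(matrix(as.numeric(mm), nrow(mm), ncol(mm)),
                       EBImage::makeBrush(3, "box")) > 0.5
  boundary <- mm & !er
  # candidate edges live within 1 px of the silhouette boundary; applying
  # the envelope before hysteresis keeps distinct loops from being linked
  # through interior gradient pixels
  env <- EBImage::dilate(matrix(as.numeric(boundary), nrow(mm), ncol(mm)),
                         EBImage::makeBrush(3, "box")) > 0.5
  strong <- keep & mag >= highThr & env
  # the interior boundary of a binary mask is always a true edge; including
  # it as weak support keeps each loop closed where the quantized
  # non-maximum suppression breaks at corners
  weak <- (keep | boundary) & mag >= lowThr & env
  lab <- label8(weak)
  strongLabs <- unique(lab[strong & lab > 0])
  matrix(lab %in% strongLabs, nrow(m), ncol(m))
}

gaussianSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k <- outer(k, k); k <- k / sum(k)
  convolve2(m, k)
}

# 2-D convolution with replicate padding (avoids EBImage's circular default).
convolve2 <- function(m, k) {
  rk <- (nrow(k) - 1L) %/% 2L; ck <- (ncol(k) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2 * rk, w + 2 * ck)
  pad[rk + seq_len(h), ck + seq_len(w)] <- m
  if (rk > 0) {
    pad[seq_len(rk), ] <- pad[rep(rk + 1L, rk), ]
    pad[h + rk + seq_len(rk), ] <- pad[rep(h + rk, rk), ]
  }
  if (ck > 0) {
    pad[, seq_len(ck)] <- pad[, rep(ck + 1L, ck)]
    pad[, w + ck + seq_len(ck)] <- pad[, rep(w + ck, ck)]
  }
  out <- matrix(0, h, w)
  for (i in seq_len(nrow(k))) for (j in seq_len(ncol(k))) {
    if (k[i, j] == 0) next
    out <- out + k[i, j] * pad[(i - 1L) + seq_len(h), (j - 1L) + seq_len(w)]
  }
  out
}

#' Skeletonize the plant silhouette
#'
#' Zhang-Suen iterative thinning to a one-pixel-wide medial axis. The
#' skeleton is always a subset of the mask and preserves the connectivity of
#' each component; a single pixel is its own skeleton.
#'
#' @param mask a [PlantMask-class].
#' @return logical skeleton matrix.
#' @export
skeletonizePlant <- function(mask) {
  stopifnot(is(mask, "PlantMask"))
  p <- maskMatrix(mask) * 1L
  if (!any(p)) return(p > 0)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9 clockwise from north
      P2 <- shiftMat(p, -1, 0); P3 <- shiftMat(p, -1, 1); P4 <- shiftMat(p, 0, 1)
      P5 <- shiftMat(p, 1, 1);  P6 <- shiftMat(p, 1, 0);  P7 <- shiftMat(p, 1, -1)
      P8 <- shiftMat(p, 0, -1); P9 <- shiftMat(p, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (step == 1) {
        cond <- P2 * P4 * P6 == 0 & P4 * P6 * P8 == 0
      } else {
        cond <- P2 * P4 * P8 == 0 & P2 * P6 * P8 == 0
      }
      del <- p == 1L & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        p[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p > 0
}

#' Hough transform parameters
#'
#' @param rhoRes distance resolution of the accumulator, pixels.
#' @param thetaResDeg angular resolution, degrees.
#' @param threshold minimum accumulator votes for a candidate line.
#' @param minLineLength minimum accepted segment length, pixels. `NULL`
#'   defers to the caller's plant-size default (0.05 x PH).
#' @param maxLineGap largest gap (pixels) bridged within one segment.
#' @return named list of parameters.
#' @export
houghParams <- function(rhoRes = 1, thetaResDeg = 1, threshold = 20,
                        minLineLength = NULL, maxLineGap = 5) {
  stopifnot(rhoRes > 0, thetaResDeg > 0, threshold >= 1, maxLineGap >= 0)
  list(rhoRes = rhoRes, thetaResDeg = thetaResDeg, threshold = threshold,
       minLineLength = minLineLength, maxLineGap = maxLineGap)
}

#' Inclination angle of a line segment
#'
#' The unsigned angle between the segment and the horizontal plane,
#' `atan(|dy| / |dx|)` in degrees, folded into [0, 90]: leaves leaning left
#' or right are equivalent. Independent of endpoint order and of uniform
#' rescaling.
#'
#' @param p1,p2 numeric `c(x, y)` endpoints; must differ.
#' @return angle in degrees, [0, 90].
#' @export
segmentAngle <- function(p1, p2) {
  dx <- abs(p2[1] - p1[1]); dy <- abs(p2[2] - p1[2])
  if (dx == 0 && dy == 0) stop("coincident endpoints have no angle")
  atan2(dy, dx) * 180 / pi
}

#' Relative height of a leaf segment midpoint
#'
#' RH = 100 x (bottomRow - midpointRow) / plant height, the midpoint height
#' above the plant bottom as a percent of plant height, clipped to
#' [0, 100].
#'
#' @param midpointRow raster row of the segment midpoint.
#' @param extent list with `topRow`, `bottomRow` (see [plantExtent()]).
#' @return percent in [0, 100].
#' @export
relativeHeight <- function(midpointRow, extent) {
  ph <- extent$bottomRow - extent$topRow
  if (ph < 1) stop("zero plant height")
  min(100, max(0, 100 * (extent$bottomRow - midpointRow) / ph))
}

#' Detect leaf line segments by a deterministic progressive Hough transform
#'
#' Builds the full (theta, rho) vote accumulator over the source raster's
#' foreground pixels, then repeatedly takes the strongest line, collects the
#' pixels within `rhoRes` of it, splits them into collinear runs at gaps
#' larger than `maxLineGap`, emits each run of span at least
#' `minLineLength` as a segment (its endpoints are the run's extreme
#' pixels, so the reported angle is not quantized to the theta grid) and
#' removes the consumed pixels. Unlike the randomized progressive Hough,
#' this is fully deterministic. Near-collinear duplicates (angular
#' difference <= 5 degrees and mutual midpoint-to-line distance <= 5 px)
#' are merged into their longest-span representative, and near-horizontal
#' segments longer than half the image width are discarded as pot-rim /
#' ground artifacts. Each surviving segment is annotated with its
#' inclination angle and relative height.
#'
#' @param lineSource logical raster (skeleton or edge map).
#' @param hough parameter list from [houghParams()].
#' @param geometry a [PlantGeometry-class]; supplies the extent for relative
#'   heights and the plant-height-scaled default `minLineLength`.
#' @param merge merge near-collinear fragments (default `TRUE`).
#' @param suppressCulm erase dominant near-vertical lines (culm/tillers)
#'   before detection; skipped automatically when the candidate would claim
#'   most of the raster, so isolated steep strokes are never deleted.
#' @param refineSource optional raster (typically the cleaned plant mask)
#'   against which accepted segments are re-extended; thinning bends stroke
#'   bases at stem junctions, and re-scanning the full mask corridor
#'   restores true endpoints and midpoints. `NULL` refines against
#'   `lineSource` itself.
#' @return data.frame with columns `p1x, p1y, p2x, p2y, midx, midy,
#'   length_px, angle_deg, rel_height`; zero rows (with a warning) when no
#'   segment is found.
#' @export
detectLeafLines <- function(lineSource, hough = houghParams(), geometry,
                            merge = TRUE, suppressCulm = TRUE,
                            refineSource = NULL) {
  stopifnot(is.matrix(lineSource))
  src <- lineSource != 0
  minLen <- hough$minLineLength %||% (0.05 * geometry@plantHeightPx)
  if (suppressCulm) src <- eraseCulm(src, geometry, hough)
  segs <- houghSegments(src, hough, minLen)
  segs <- refineSegments(segs, if (is.null(refineSource)) src
                         else refineSource != 0, hough)
  if (merge && nrow(segs) > 1) segs <- mergeSegments(segs)
  if (suppressCulm && nrow(segs) > 0) {
    # scene-furniture filters (after merging, so fragmented furniture is
    # seen at full span): long near-horizontal lines are pot-rim/ground
    # artifacts; long near-vertical lines are the culm/stem, not leaves.
    # Gated on suppressCulm: with it off the caller asserts the scene has
    # no furniture, so steep or flat strokes are genuine.
    keepIdx <- !(segs$angle_deg < 2 & segs$length_px > 0.5 * ncol(src)) &
      !(segs$angle_deg > 88 & segs$length_px > 0.4 * geometry@plantHeightPx)
    segs <- segs[keepIdx, , drop = FALSE]
  }
  if (nrow(segs) == 0) {
    warning("no leaf line segments detected")
    return(data.frame(p1x = numeric(0), p1y = numeric(0), p2x = numeric(0),
                      p2y = numeric(0), midx = numeric(0), midy = numeric(0),
                      length_px = numeric(0), angle_deg = numeric(0),
                      rel_height = numeric(0)))
  }
  ext <- list(topRow = geometry@topRow, bottomRow = geometry@bottomRow)
  segs$rel_height <- vapply(segs$midy, relativeHeight, numeric(1), extent = ext)
  rownames(segs) <- NULL
  segs
}

# Erase dominant near-vertical lines (the culm / tillers) from the line
# source before leaf detection: a vertical structure spanning a large share
# of the plant height is stem, not leaf, and its junction remnants otherwise
# contaminate the angle samples. Erasure is skipped when the candidate would
# remove more than 30% of the raster -- a culm is always a minority of the
# skeleton, so a lone steep stroke (a valid leaf) is never deleted.
eraseCulm <- function(src, geometry, hough, corridor = 2, maxIter = 5) {
  for (iter in seq_len(maxIter)) {
    if (!any(src)) break
    ys <- rowIndexMat(src)[src]
    xs <- colIndexMat(src)[src]
    thetaDeg <- c(0, 1, 2, 178, 179)
    th <- thetaDeg * pi / 180
    rho <- outer(xs, cos(th)) + outer(ys, sin(th))
    best <- NULL
    for (j in seq_along(th)) {
      rb <- round(rho[, j])
      cnt <- table(rb)
      k <- which.max(cnt)
      if (is.null(best) || cnt[k] > best$votes)
        best <- list(votes = as.integer(cnt[k]),
                     rho = as.numeric(names(cnt)[k]), j = j)
    }
    if (best$votes < 0.4 * geometry@plantHeightPx) break
    sel <- abs(rho[, best$j] - best$rho) <= corridor
    if (sum(sel) > 0.3 * length(xs)) break
    src[cbind(ys[sel], xs[sel])] <- FALSE
  }
  src
}

# Core accumulator loop; returns raw segments (no merge, no annotation).
houghSegments <- function(src, hough, minLen) {
  empty <- data.frame(p1x = numeric(0), p1y = numeric(0), p2x = numeric(0),
                      p2y = numeric(0), midx = numeric(0), midy = numeric(0),
                      length_px = numeric(0), angle_deg = numeric(0))
  if (!any(src)) return(empty)
  ys <- rowIndexMat(src)[src]
  xs <- colIndexMat(src)[src]
  np <- length(xs)
  thetas <- seq(0, 180 - hough$thetaResDeg, by = hough$thetaResDeg) * pi / 180
  nt <- length(thetas)
  rho <- outer(xs, cos(thetas)) + outer(ys, sin(thetas))   # np x nt
  D <- ceiling(sqrt(nrow(src)^2 + ncol(src)^2) / hough$rhoRes)
  rbin <- round(rho / hough$rhoRes) + D + 1L               # 1 .. 2D+1
  nr <- 2L * D + 1L
  binIdx <- matrix(as.integer((col(rbin) - 1L) * nr + rbin), np, nt)
  nbins <- nr * nt
  active <- rep(TRUE, np)
  suppressed <- integer(0)
  segs <- list()
  for (iter in seq_len(1000L)) {
    counts <- tabulate(binIdx[active, ], nbins = nbins)
    if (length(suppressed)) counts[suppressed] <- 0L
    best <- which.max(counts)
    if (counts[best] < hough$threshold) break
    tIdx <- (best - 1L) %/% nr + 1L
    rIdx <- best - (tIdx - 1L) * nr
    rhoPeak <- (rIdx - D - 1L) * hough$rhoRes
    near <- active & abs(rho[, tIdx] - rhoPeak) <= hough$rhoRes
    idx <- which(near)
    # position along the line direction (-sin t, cos t)
    tpos <- -xs[idx] * sin(thetas[tIdx]) + ys[idx] * cos(thetas[tIdx])
    o <- order(tpos)
    idx <- idx[o]; tpos <- tpos[o]
    runBreaks <- c(0L, which(diff(tpos) > hough$maxLineGap), length(idx))
    found <- FALSE
    for (k in seq_len(length(runBreaks) - 1L)) {
      sel <- idx[(runBreaks[k] + 1L):runBreaks[k + 1L]]
      if (length(sel) < 2L) next
      a <- sel[1L]; bpt <- sel[length(sel)]
      len <- sqrt((xs[bpt] - xs[a])^2 + (ys[bpt] - ys[a])^2)
      if (len < minLen) next
      segs[[length(segs) + 1L]] <-
        c(xs[a], ys[a], xs[bpt], ys[bpt],
          (xs[a] + xs[bpt]) / 2, (ys[a] + ys[bpt]) / 2, len,
          segmentAngle(c(xs[a], ys[a]), c(xs[bpt], ys[bpt])))
      active[sel] <- FALSE
      found <- TRUE
    }
    if (!found) suppressed <- c(suppressed, best)
  }
  if (length(segs) == 0) return(empty)
  out <- as.data.frame(do.call(rbind, segs))
  names(out) <- c("p1x", "p1y", "p2x", "p2y", "midx", "midy",
                  "length_px", "angle_deg")
  out
}

# Re-extend each detected segment against the full source raster. The
# progressive accumulator consumes pixels, so a stroke crossed by an
# earlier detection comes out shortened with a shifted midpoint; here the
# segment's collinear corridor is re-scanned over all pixels and the
# endpoints grow to the full gap-bridged run containing the segment.
refineSegments <- function(segs, src, hough) {
  if (nrow(segs) == 0) return(segs)
  ys <- rowIndexMat(src)[src]
  xs <- colIndexMat(src)[src]
  for (i in seq_len(nrow(segs))) {
    dx <- segs$p2x[i] - segs$p1x[i]; dy <- segs$p2y[i] - segs$p1y[i]
    nl <- sqrt(dx^2 + dy^2)
    ux <- dx / nl; uy <- dy / nl
    d <- abs(uy * (xs - segs$p1x[i]) - ux * (ys - segs$p1y[i]))
    sel <- which(d <= hough$rhoRes)
    t <- (xs[sel] - segs$p1x[i]) * ux + (ys[sel] - segs$p1y[i]) * uy
    o <- order(t)
    sel <- sel[o]; t <- t[o]
    breaks <- c(0L, which(diff(t) > hough$maxLineGap), length(sel))
    tMid <- nl / 2
    for (k in seq_len(length(breaks) - 1L)) {
      ii <- (breaks[k] + 1L):breaks[k + 1L]
      if (t[ii[1]] - 1e-9 <= tMid && tMid <= t[ii[length(ii)]] + 1e-9) {
        a <- sel[ii[1]]; b <- sel[ii[length(ii)]]
        segs$p1x[i] <- xs[a]; segs$p1y[i] <- ys[a]
        segs$p2x[i] <- xs[b]; segs$p2y[i] <- ys[b]
        segs$midx[i] <- (xs[a] + xs[b]) / 2
        segs$midy[i] <- (ys[a] + ys[b]) / 2
        segs$length_px[i] <- sqrt((xs[b] - xs[a])^2 + (ys[b] - ys[a])^2)
        segs$angle_deg[i] <- segmentAngle(c(xs[a], ys[a]), c(xs[b], ys[b]))
        break
      }
    }
  }
  segs
}

# Merge near-collinear duplicate detections of a single leaf.
mergeSegments <- function(segs, angleTol = 5, distTol = 5) {
  n <- nrow(segs)
  pairs <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dAng <- abs(segs$angle_deg[i] - segs$angle_deg[j])
    dAng <- min(dAng, 180 - dAng)
    if (dAng > angleTol) next
    di <- pointLineDistance(segs$midx[j], segs$midy[j],
                            segs[i, c("p1x", "p1y", "p2x", "p2y")])
    dj <- pointLineDistance(segs$midx[i], segs$midy[i],
                            segs[j, c("p1x", "p1y", "p2x", "p2y")])
    if (max(di, dj) <= distTol) pairs <- rbind(pairs, c(i, j))
  }
  if (is.null(pairs)) return(segs)
  g <- igraph::graph_from_edgelist(matrix(as.character(pairs), ncol = 2),
                                   directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(seq_len(n)),
                                    igraph::V(g)$name))
  memb <- igraph::components(g)$membership
  cluster <- integer(n)
  cluster[as.integer(names(memb))] <- as.integer(memb)
  merged <- lapply(split(seq_len(n), cluster), function(ii) {
    if (length(ii) == 1L) return(segs[ii, , drop = FALSE])
    rep <- ii[which.max(segs$length_px[ii])]      # longest-span representative
    dx <- segs$p2x[rep] - segs$p1x[rep]; dy <- segs$p2y[rep] - segs$p1y[rep]
    nl <- sqrt(dx^2 + dy^2); ux <- dx / nl; uy <- dy / nl
    ex <- c(segs$p1x[ii], segs$p2x[ii]); ey <- c(segs$p1y[ii], segs$p2y[ii])
    t <- (ex - segs$p1x[rep]) * ux + (ey - segs$p1y[rep]) * uy
    lo <- which.min(t); hi <- which.max(t)
    p1 <- c(segs$p1x[rep] + t[lo] * ux, segs$p1y[rep] + t[lo] * uy)
    p2 <- c(segs$p1x[rep] + t[hi] * ux, segs$p1y[rep] + t[hi] * uy)
    data.frame(p1x = p1[1], p1y = p1[2], p2x = p2[1], p2y = p2[2],
               midx = (p1[1] + p2[1]) / 2, midy = (p1[2] + p2[2]) / 2,
               length_px = sqrt(sum((p2 - p1)^2)),
               angle_deg = segmentAngle(p1, p2))
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

pointLineDistance <- function(px, py, seg) {
  seg <- as.numeric(seg)
  dx <- seg[3] - seg[1]; dy <- seg[4] - seg[2]
  nl <- sqrt(dx^2 + dy^2)
  if (nl == 0) return(sqrt((px - seg[1])^2 + (py - seg[2])^2))
  abs(dy * (px - seg[1]) - dx * (py - seg[2])) / nl
}
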