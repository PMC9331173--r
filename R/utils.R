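# Internal raster helpers shared across modules.

# Shift a matrix by (dr, dc), padding with `fill`. Positive dr moves content
# down (towards larger row indices), positive dc to the right.
shiftMat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rsrc <- seq_len(h) - dr
  csrc <- seq_len(w) - dc
  rok <- rsrc >= 1 & rsrc <= h
  cok <- csrc >= 1 & csrc <= w
  out[rok, cok] <- m[rsrc[rok], csrc[cok]]
  out
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, which
# splits Bresenham-rasterised diagonal strokes; diagonal-touching labels are
# therefore merged afterwards.
label8 <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  pairs <- NULL
  for (d in list(c(1, 1), c(1, -1))) {
    sh <- shiftMat(lab, d[1], d[2], fill = 0L)
    sel <- lab > 0L & sh > 0L & lab != sh
    if (any(sel)) pairs <- rbind(pairs, cbind(lab[sel], sh[sel]))
  }
  if (is.null(pairs)) return(lab)
  g <- igraph::graph_from_edgelist(matrix(as.character(pairs), ncol = 2),
                                   directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(seq_len(nl)),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  map <- integer(nl)
  map[as.integer(names(comp))] <- as.integer(comp)
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

# Areas of labelled components, index i = label i.
componentAreas <- function(lab) {
  nl <- max(lab)
  if (nl == 0L) return(integer(0))
  tabulate(lab[lab > 0L], nbins = nl)
}

# Keep the largest 8-connected component (ties broken by lowest label).
largestComponent <- function(mask) {
  lab <- label8(mask)
  ar <- componentAreas(lab)
  if (length(ar) == 0L) return(mask & FALSE)
  lab == which.max(ar)
}

# Arc length of an 8-connected boundary chain (closed polyline): unit steps
# for axis moves, sqrt(2) for diagonal moves. Single point => length 1 by
# the documented degenerate rule.
chainArcLength <- function(pts) {
  n <- nrow(pts)
  if (n <= 1L) return(1)
  d <- pts[c(2:n, 1L), , drop = FALSE] - pts
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

# Row/column index matrices for a mask's dimensions.
rowIndexMat <- function(mask) matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
colIndexMat <- function(mask) matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask),
                                     byrow = TRUE)

# Convert an H x W x 3 array in [0,1] to HSV with hue in degrees [0, 360).
rgbArrayToHsv <- function(img) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] >= 3)
  rgb <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  list(h = hsv[1, ] * 360, s = hsv[2, ], v = hsv[3, ],
       dim = dim(img)[1:2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
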