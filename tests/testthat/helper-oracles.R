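# Shared fixtures and independent brute-force oracles.

# logical H x W matrix with TRUE at the given (row, col) index matrix
maskFromPixels <- function(h, w, rc) {
  m <- matrix(FALSE, h, w)
  m[rc] <- TRUE
  m
}

rectMask <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  m
}

# brute-force RHC: mean over foreground pixels (within extent rows) of
# (bottom - row) / (bottom - top)
rhcOracle <- function(m, top, bottom) {
  rows <- row(m)[m]
  rows <- rows[rows >= top & rows <= bottom]
  mean((bottom - rows) / (bottom - top))
}

# independent 8-connected labelling by explicit BFS flood fill
bfsLabelOracle <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  nextLab <- 0L
  for (idx in which(m)) {
    if (lab[idx] > 0L) next
    nextLab <- nextLab + 1L
    queue <- idx
    lab[idx] <- nextLab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %% nrow(m) + 1L
      c <- (cur - 1L) %/% nrow(m) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m) &&
            m[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nextLab
          queue <- c(queue, (cc - 1L) * nrow(m) + rr)
        }
      }
    }
  }
  lab
}

# closed-form OLS on a single regressor via the normal equations
olsOracle <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))   # (intercept, slope)
}

# multi-feature normal-equation OLS
mlrOracle <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  as.numeric(solve(t(X1) %*% X1, t(X1) %*% y))
}

# random connected-ish blob mask: union of filled discs on a seeded walk
randomBlobMask <- function(seed, h = 80, w = 80, steps = 12) {
  set.seed(seed)
  m <- matrix(FALSE, h, w)
  r <- runif(1, h * 0.3, h * 0.7); c <- runif(1, w * 0.3, w * 0.7)
  for (i in seq_len(steps)) {
    rad <- runif(1, 2, 6)
    rr <- pmax(1, pmin(h, round(r + (-10:10))))
    for (dr in -ceiling(rad):ceiling(rad)) for (dc in -ceiling(rad):ceiling(rad)) {
      if (dr^2 + dc^2 <= rad^2) {
        pr <- round(r) + dr; pc <- round(c) + dc
        if (pr >= 1 && pr <= h && pc >= 1 && pc <= w) m[pr, pc] <- TRUE
      }
    }
    r <- min(h - 5, max(5, r + runif(1, -8, 8)))
    c <- min(w - 5, max(5, c + runif(1, -8, 8)))
  }
  m
}

# uniform-colour H x W x 3 image
uniformImage <- function(h, w, rgb) {
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# image whose foreground pixels carry the given colour on mid-grey
imageFromMask <- function(m, fg = c(0.25, 0.72, 0.30), bg = rep(0.5, 3)) {
  img <- array(0, c(nrow(m), ncol(m), 3))
  for (ch in 1:3) {
    plane <- matrix(bg[ch], nrow(m), ncol(m))
    plane[m] <- fg[ch]
    img[, , ch] <- plane
  }
  img
}

# point-in-convex-polygon test (allows boundary), polygon as (x, y) rows
insideConvexPolygon <- function(px, py, poly, tol = 1e-9) {
  n <- nrow(poly)
  if (n < 3) return(TRUE)
  sgn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) -
      (poly[j, 2] - poly[i, 2]) * (px - poly[i, 1])
    if (abs(cr) < tol) next
    s <- sign(cr)
    if (sgn == 0) sgn <- s else if (s != sgn) return(FALSE)
  }
  TRUE
}

# raster with one straight stroke of given inclination through the centre
strokeRaster <- function(angleDeg, len = 80, size = 200, width = 2) {
  a <- angleDeg * pi / 180
  cx <- size / 2; cy <- size / 2
  p1 <- c(cx - len / 2 * cos(a), cy + len / 2 * sin(a))
  p2 <- c(cx + len / 2 * cos(a), cy - len / 2 * sin(a))
  lab <- matrix(0L, size, size)
  lab <- vertphen:::paintStroke(lab, p1, p2, width, 1L)
  lab > 0L
}
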