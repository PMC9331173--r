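test_that("contour of simple shapes matches boundary-pixel counts", {
  sq <- PlantMask(rectMask(20, 20, 6:15, 6:15))   # 10x10 filled square
  ct <- extractContour(sq)
  # boundary pixels: those with at least one background 4-neighbour
  expect_equal(nrow(ct), 36)
  geo <- plantGeometry(sq, droopQuantile = 0)
  expect_equal(geo@perimeterPx, 36)

  single <- PlantMask(maskFromPixels(10, 10, cbind(5, 5)))
  ct1 <- extractContour(single)
  expect_equal(nrow(ct1), 1)

  # two disjoint blobs: contour of the larger only
  m <- rectMask(30, 30, 2:11, 2:11)
  m[20:22, 20:22] <- TRUE
  ct2 <- extractContour(PlantMask(m))
  expect_true(all(ct2[, 1] <= 11 & ct2[, 2] <= 11))

  expect_error(extractContour(PlantMask(matrix(FALSE, 4, 4))), "empty")
})

test_that("convex hull contains every input point", {
  sqPts <- as.matrix(expand.grid(x = 1:10, y = 1:10))
  hull <- convexHullPolygon(sqPts)
  expect_equal(nrow(hull), 4)
  expect_setequal(paste(hull[, 1], hull[, 2]),
                  c("1 1", "1 10", "10 1", "10 10"))

  coll <- cbind(x = 1:7, y = 2 * (1:7))
  hull2 <- convexHullPolygon(coll)
  expect_lte(nrow(hull2), 2)

  set.seed(21)
  pts <- cbind(x = runif(200, 0, 50), y = runif(200, 0, 50))
  hull3 <- convexHullPolygon(pts)
  for (i in seq_len(nrow(pts)))
    expect_true(insideConvexPolygon(pts[i, 1], pts[i, 2], hull3, tol = 1e-7))
})

test_that("plant extent applies droop-quantile row filtering", {
  bar <- PlantMask(rectMask(200, 100, 10:109, 1:100))
  e0 <- plantExtent(bar, 0)
  expect_equal(c(e0$topRow, e0$bottomRow, e0$plantHeightPx), c(10, 109, 99))

  # 1-px drooping tail (41 px < 0.5% of 10041 foreground pixels)
  tail <- rectMask(200, 100, 10:109, 1:100)
  tail[110:150, 50] <- TRUE
  eTail <- plantExtent(PlantMask(tail), 0.005)
  expect_equal(eTail$bottomRow, 109)
  # row-histogram quantile oracle
  rows <- row(tail)[tail]
  expect_equal(eTail$bottomRow,
               as.numeric(quantile(rows, 0.995, type = 1)))
  # droopQuantile = 0 keeps the tail
  expect_equal(plantExtent(PlantMask(tail), 0)$bottomRow, 150)

  expect_error(plantExtent(PlantMask(rectMask(10, 10, 5, 2:8)), 0), "single row")
})

test_that("centroid is the binary-moment mean of pixel coordinates", {
  rect <- PlantMask(rectMask(30, 30, 1:10, 1:20))
  expect_equal(computeCentroid(rect), c(10.5, 5.5))

  two <- PlantMask(maskFromPixels(20, 20, cbind(c(1, 11), c(7, 7))))
  expect_equal(computeCentroid(two)[2], 6)

  for (seed in 1:5) {
    m <- randomBlobMask(seed)
    cen <- computeCentroid(PlantMask(m))
    expect_equal(cen[1], mean(col(m)[m]), tolerance = 1e-9)
    expect_equal(cen[2], mean(row(m)[m]), tolerance = 1e-9)
  }
})

test_that("RHC equals the brute-force pixel-mean height ratio", {
  rect <- PlantMask(rectMask(40, 20, 11:30, 5:15))
  expect_identical(computeRHC(rect, plantExtent(rect, 0)), 0.5)

  # mass only in the top 10% of a 200-row span
  strip <- PlantMask(rectMask(220, 50, 11:30, 10:40))
  ext <- list(topRow = 11, bottomRow = 210)
  expect_equal(computeRHC(strip, ext), 0.95, tolerance = 1 / 200)

  for (seed in 1:8) {
    m <- randomBlobMask(seed)
    pm <- PlantMask(m)
    ext <- plantExtent(pm, 0)
    expect_equal(computeRHC(pm, ext),
                 rhcOracle(m, ext$topRow, ext$bottomRow), tolerance = 1e-9)
  }
})

test_that("RHC is invariant under translation, mirroring and rescaling", {
  m <- randomBlobMask(42)
  pm <- PlantMask(m)
  base <- computeRHC(pm, plantExtent(pm, 0))

  shifted <- m[, c(11:ncol(m), 1:10)]           # horizontal translation
  expect_equal(computeRHC(PlantMask(shifted),
                          plantExtent(PlantMask(shifted), 0)), base,
               tolerance = 1e-12)

  mirrored <- m[, ncol(m):1]
  expect_equal(computeRHC(PlantMask(mirrored),
                          plantExtent(PlantMask(mirrored), 0)), base,
               tolerance = 1e-12)

  doubled <- m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
  pmd <- PlantMask(doubled)
  ph <- plantExtent(pm, 0)$plantHeightPx
  expect_equal(computeRHC(pmd, plantExtent(pmd, 0)), base, tolerance = 2 / ph)
})

test_that("moving mass upward weakly increases RHC", {
  set.seed(5)
  for (rep in 1:10) {
    m <- randomBlobMask(rep + 100)
    pm <- PlantMask(m)
    ext <- plantExtent(pm, 0)
    base <- computeRHC(pm, ext)
    # move one interior foreground pixel strictly upward within the extent
    cand <- which(m & row(m) > ext$topRow + 1 & row(m) < ext$bottomRow)
    cand <- cand[!m[cand - 1L]]
    if (length(cand) == 0) next
    i <- cand[1]
    m2 <- m; m2[i] <- FALSE; m2[i - 1L] <- TRUE
    expect_gte(computeRHC(PlantMask(m2), ext), base)
  }
})

test_that("geometry invariants hold on random blobs", {
  for (seed in 1:6) {
    m <- randomBlobMask(seed + 30)
    geo <- plantGeometry(PlantMask(m), droopQuantile = 0)
    expect_gt(geo@rhc, 0); expect_lt(geo@rhc, 1)
    expect_gte(geo@plantHeightPx, 1)
    expect_true(insideConvexPolygon(geo@centroid[1], geo@centroid[2],
                                    geo@hull, tol = 1e-7))
  }
})
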