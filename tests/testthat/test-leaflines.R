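test_that("edges trace the silhouette boundary", {
  rect <- PlantMask(rectMask(40, 40, 10:29, 8:31))
  ed <- detectEdges(rect)
  expect_true(any(ed))
  # every edge pixel lies within 1 px of the morphological boundary
  m <- maskMatrix(rect)
  boundary <- m & !(EBImage::erode(matrix(as.numeric(m), 40, 40),
                                   EBImage::makeBrush(3, "box")) > 0.5)
  env <- EBImage::dilate(matrix(as.numeric(boundary), 40, 40),
                         EBImage::makeBrush(3, "box")) > 0.5
  expect_true(all(!ed | env))

  # hollow ring of width 3: two concentric boundary loops
  ring <- rectMask(40, 40, 8:31, 8:31)
  ring[11:28, 11:28] <- FALSE
  edr <- detectEdges(PlantMask(ring))
  expect_equal(max(vertphen:::label8(edr)), 2)
})

test_that("edge pixels stay within 2 px of synthetic stroke boundaries", {
  g <- generatePlant(syntheticPlantSpec(seed = 2))
  mask <- PlantMask(g$truth@raster)
  ed <- detectEdges(mask)
  m <- g$truth@raster
  boundary <- m & !(EBImage::erode(matrix(as.numeric(m), nrow(m), ncol(m)),
                                   EBImage::makeBrush(3, "box")) > 0.5)
  env <- EBImage::dilate(matrix(as.numeric(boundary), nrow(m), ncol(m)),
                         EBImage::makeBrush(5, "box")) > 0.5
  expect_true(all(!ed | env))
})

test_that("skeleton is a thin medial subset preserving connectivity", {
  bar <- PlantMask(rectMask(20, 60, 8:12, 5:56))   # 5-px-wide horizontal bar
  sk <- skeletonizePlant(bar)
  skPix <- which(sk, arr.ind = TRUE)
  # middle row through the bar interior
  expect_true(all(skPix[, 1] == 10))
  expect_true(all(sk[10, 10:50]))

  single <- PlantMask(maskFromPixels(9, 9, cbind(4, 4)))
  expect_identical(which(skeletonizePlant(single)), which(maskMatrix(single)))

  plus <- matrix(FALSE, 41, 41)
  plus[19:23, 6:36] <- TRUE
  plus[6:36, 19:23] <- TRUE
  skp <- skeletonizePlant(PlantMask(plus))
  expect_true(all(skp[21, 10:32] | skp[20, 10:32] | skp[22, 10:32]))
  expect_true(all(skp[10:32, 21] | skp[10:32, 20] | skp[10:32, 22]))
  expect_true(all(!skp | plus))

  for (seed in 1:4) {
    m <- randomBlobMask(seed + 60)
    sk <- skeletonizePlant(PlantMask(m))
    expect_true(all(!sk | m))                      # subset of the mask
    expect_equal(max(vertphen:::label8(sk)),       # connectivity preserved
                 max(vertphen:::label8(m)))
  }
})

test_that("Hough recovers a single stroke and keeps parallel strokes apart", {
  src <- strokeRaster(30, len = 80)
  geo <- plantGeometry(PlantMask(src), droopQuantile = 0)
  segs <- detectLeafLines(src, houghParams(), geo)
  expect_equal(nrow(segs), 1)
  expect_lt(abs(segs$angle_deg - 30), 2)

  blank <- matrix(FALSE, 50, 50)
  expect_warning(none <- detectLeafLines(blank, houghParams(), geo), "no leaf")
  expect_equal(nrow(none), 0)

  # two parallel strokes 40 px apart perpendicular: never merged
  lab <- matrix(0L, 200, 200)
  lab <- vertphen:::paintStroke(lab, c(40, 160), c(110, 90), 2, 1L)
  lab <- vertphen:::paintStroke(lab, c(96, 188), c(166, 118), 2, 1L)
  two <- lab > 0L
  geo2 <- plantGeometry(PlantMask(two), droopQuantile = 0)
  segs2 <- detectLeafLines(two, houghParams(), geo2)
  expect_equal(nrow(segs2), 2)
})

test_that("segment inclination is folded, order-free and scale-free", {
  expect_equal(segmentAngle(c(0, 0), c(10, 0)), 0)
  expect_equal(segmentAngle(c(0, 0), c(0, 10)), 90)
  expect_equal(segmentAngle(c(0, 0), c(10, 10)), 45)
  expect_error(segmentAngle(c(3, 3), c(3, 3)), "coincident")
  for (ang in seq(5, 85, by = 10)) {
    p2 <- c(cos(ang * pi / 180), sin(ang * pi / 180)) * 50
    a1 <- segmentAngle(c(0, 0), p2)
    expect_equal(a1, ang, tolerance = 1e-9)
    expect_equal(segmentAngle(p2, c(0, 0)), a1)           # endpoint order
    expect_equal(segmentAngle(c(0, 0), p2 * 3.7), a1)     # uniform rescale
    expect_equal(segmentAngle(c(0, 0), c(-p2[1], p2[2])), a1)  # mirror fold
  }
})

test_that("relative height maps the extent to [0, 100]", {
  ext <- list(topRow = 20, bottomRow = 120)
  expect_equal(relativeHeight(120, ext), 0)
  expect_equal(relativeHeight(20, ext), 100)
  expect_equal(relativeHeight(70, ext), 50)
  expect_equal(relativeHeight(150, ext), 0)      # clipped below
  expect_equal(relativeHeight(5, ext), 100)      # clipped above
  expect_error(relativeHeight(10, list(topRow = 5, bottomRow = 5)), "zero")
})

test_that("most strokes of a synthetic plant are recovered within tolerance", {
  for (case in list(c(5, 20, 1), c(10, 30, 3), c(15, 10, 1))) {
    g <- generatePlant(syntheticPlantSpec(aTrue = case[1], bTrue = case[2],
                                          seed = case[3]))
    res <- analyzePlantImage(g$image)
    segs <- res$segments
    ext <- list(topRow = res$geometry@topRow, bottomRow = res$geometry@bottomRow)
    tr <- g$truth@leaves
    trRel <- vapply(tr$mid_y, relativeHeight, numeric(1), extent = ext)
    hits <- vapply(seq_len(nrow(tr)), function(i)
      any(abs(segs$angle_deg - tr$angle_deg[i]) <= 3 &
            abs(segs$rel_height - trRel[i]) <= 3), logical(1))
    expect_gte(mean(hits), 0.8)
    expect_true(all(segs$rel_height >= 0 & segs$rel_height <= 100))
    expect_true(all(segs$angle_deg >= 0 & segs$angle_deg <= 90))
  }
})
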