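test_that("uniform colours segment trivially", {
  green <- uniformImage(6, 8, c(0.2, 0.8, 0.2))
  m <- segmentPlant(green)
  expect_true(all(maskMatrix(m)))
  expect_false(isEmptyMask(m))

  blue <- uniformImage(6, 8, c(0.1, 0.1, 0.9))
  expect_warning(m2 <- segmentPlant(blue), "empty")
  expect_false(any(maskMatrix(m2)))
  expect_true(isEmptyMask(m2))

  expect_error(segmentPlant(array(0, c(0, 3, 3))), "nonempty")
})

test_that("segmentation reproduces the generator's stroke raster", {
  g <- generatePlant(syntheticPlantSpec(seed = 3))
  m <- segmentPlant(g$image)
  expect_identical(maskMatrix(m), g$truth@raster)

  # senescent plant: both green and yellow organs inside a widened hue box
  gs <- generatePlant(syntheticPlantSpec(seed = 4, greenFraction = 0.5))
  ms <- segmentPlant(gs$image, hsvThresholds(hueLo = 40))
  expect_identical(maskMatrix(ms), gs$truth@raster)
})

test_that("segmentation is idempotent on mask-coloured images", {
  for (seed in 1:5) {
    m <- randomBlobMask(seed)
    img <- imageFromMask(m)
    expect_identical(maskMatrix(segmentPlant(img)), m)
  }
})

test_that("cleanMask removes small components and can be the identity", {
  m <- matrix(FALSE, 200, 200)
  m[50:149, 50:149] <- TRUE                      # 10000-px blob
  specks <- cbind(c(5, 5, 190, 10, 180), c(5, 190, 5, 100, 180))
  for (i in seq_len(nrow(specks)))
    m[specks[i, 1] + 0:2, specks[i, 2]] <- TRUE  # five 3-px specks
  cleaned <- cleanMask(PlantMask(m), minComponentArea = 50, closingRadius = 0)
  expect_equal(sum(maskMatrix(cleaned)), 10000)
  expect_true(all(maskMatrix(cleaned)[50:149, 50:149]))

  ident <- cleanMask(PlantMask(m), minComponentArea = 0, closingRadius = 0)
  expect_identical(maskMatrix(ident), m)
})

test_that("area filter agrees with a BFS labelling oracle and is monotone", {
  set.seed(11)
  m <- matrix(runif(60 * 60) < 0.08, 60, 60)
  lab <- bfsLabelOracle(m)
  areas <- tabulate(lab[lab > 0])
  for (thr in c(1, 2, 4, 8)) {
    cleaned <- maskMatrix(cleanMask(PlantMask(m), minComponentArea = thr,
                                    closingRadius = 0))
    keep <- which(areas >= thr)
    expect_identical(cleaned, matrix(lab %in% keep, 60, 60))
  }
  # threshold larger than every component -> empty mask
  allGone <- cleanMask(PlantMask(m), minComponentArea = max(areas) + 1,
                       closingRadius = 0)
  expect_true(isEmptyMask(allGone))
  # monotone: larger threshold gives a subset mask
  prev <- maskMatrix(cleanMask(PlantMask(m), 1, 0))
  for (thr in c(2, 4, 8)) {
    cur <- maskMatrix(cleanMask(PlantMask(m), thr, 0))
    expect_true(all(!cur | prev))
    prev <- cur
  }
})

test_that("cleaning stays inside the closing-dilation envelope", {
  for (seed in 1:4) {
    m <- randomBlobMask(seed)
    cleaned <- maskMatrix(cleanMask(PlantMask(m), minComponentArea = 10,
                                    closingRadius = 2))
    env <- EBImage::dilate(matrix(as.numeric(m), nrow(m), ncol(m)),
                           EBImage::makeBrush(5, "disc")) > 0.5
    expect_true(all(!cleaned | env))
  }
})

test_that("green submask isolates green organs and is a subset of the mask", {
  m <- rectMask(20, 20, 5:14, 3:18)
  img <- imageFromMask(m)
  # half the plant recoloured senescent yellow (hue ~ 55 degrees)
  yellow <- m & col(m) >= 11
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[yellow] <- c(0.90, 0.83, 0.10)[ch]
    img[, , ch] <- plane
  }
  plant <- segmentPlant(img, hsvThresholds(hueLo = 40))
  expect_identical(maskMatrix(plant), m)
  green <- greenFractionMask(img, plant)
  expect_equal(sum(maskMatrix(green)), sum(m) / 2)
  expect_true(all(!maskMatrix(green) | maskMatrix(plant)))

  # generator labels are the oracle for a senescent synthetic plant
  g <- generatePlant(syntheticPlantSpec(seed = 9, greenFraction = 0.4))
  plantMask <- PlantMask(g$truth@raster)
  gm <- greenFractionMask(g$image, plantMask)
  expect_identical(maskMatrix(gm), g$truth@labels == 1L)

  expect_error(greenFractionMask(img, PlantMask(matrix(TRUE, 3, 3))), "dimensions")
})
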