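test_that("degenerate groupings follow the limiting convention", {
  tbl <- data.frame(group = rep(c("WF", "WS"), each = 3), rhc = 0.5)
  cmp <- anovaTukey(tbl, "rhc")
  expect_equal(cmp@fStatistic, 0)
  expect_equal(cmp@pValue, 1)
  expect_true(cmp@degenerate)
  expect_equal(cmp@stars, "")

  tbl2 <- data.frame(group = rep(c("WF", "WS"), each = 3),
                     y = rep(c(0, 10), each = 3))
  cmp2 <- anovaTukey(tbl2, "y")
  expect_equal(cmp2@pValue, 0)
  expect_equal(cmp2@stars, "***")
  expect_true(cmp2@degenerate)

  expect_error(anovaTukey(data.frame(group = "A", y = 1), "y"), "2 groups")
})

test_that("ANOVA F and Tukey p match hand-computed oracles", {
  set.seed(31)
  tbl <- data.frame(group = rep(c("WF", "WM", "WS"), each = 8),
                    y = rnorm(24, rep(c(10, 12, 15), each = 8), 2))
  cmp <- anovaTukey(tbl, "y")

  # textbook sums of squares
  gm <- mean(tbl$y)
  means <- tapply(tbl$y, tbl$group, mean)
  ssb <- sum(8 * (means - gm)^2)
  ssw <- sum((tbl$y - means[tbl$group])^2)
  fOracle <- (ssb / 2) / (ssw / 21)
  expect_equal(cmp@fStatistic, fOracle, tolerance = 1e-9)
  expect_equal(cmp@pValue, pf(fOracle, 2, 21, lower.tail = FALSE),
               tolerance = 1e-9)

  # Tukey studentized-range oracle per pair
  mse <- ssw / 21
  for (i in seq_len(nrow(cmp@tukey))) {
    pair <- strsplit(cmp@tukey$pair[i], "-")[[1]]
    q <- unname(abs(means[pair[1]] - means[pair[2]])) / sqrt(mse / 8)
    expect_equal(cmp@tukey$p_adj[i],
                 ptukey(q, nmeans = 3, df = 21, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("ANOVA p is invariant to constant shifts and group relabelling", {
  set.seed(8)
  tbl <- data.frame(group = rep(c("A", "B", "C"), each = 6), y = rnorm(18))
  p0 <- anovaTukey(tbl, "y")@pValue
  shifted <- tbl; shifted$y <- shifted$y + 100
  expect_equal(anovaTukey(shifted, "y")@pValue, p0, tolerance = 1e-12)
  relab <- tbl; relab$group <- chartr("ABC", "ZYX", relab$group)
  expect_equal(anovaTukey(relab, "y")@pValue, p0, tolerance = 1e-12)
})

test_that("MLR equals the normal-equation solution and r = 1 when exact", {
  set.seed(12)
  tbl <- data.frame(rhc = runif(30, 0.3, 0.7), ph = runif(30, 200, 400),
                    gpar = runif(30, 0.5, 1))
  tbl$adm <- 2 + 5 * tbl$rhc + 0.01 * tbl$ph - 3 * tbl$gpar
  fit <- mlrFit(tbl, c("rhc", "ph", "gpar"), "adm")
  expect_equal(fit@pearsonR, 1, tolerance = 1e-12)
  expect_equal(unname(fit@coefficients), c(2, 5, 0.01, -3), tolerance = 1e-9)

  tbl$admNoisy <- tbl$adm + rnorm(30, 0, 1)
  fitN <- mlrFit(tbl, c("rhc", "ph", "gpar"), "admNoisy")
  expect_equal(unname(fitN@coefficients),
               mlrOracle(tbl[, c("rhc", "ph", "gpar")], tbl$admNoisy),
               tolerance = 1e-9)

  # single feature equal to the response
  tbl$self <- tbl$adm
  fitS <- mlrFit(tbl, "self", "adm")
  expect_equal(unname(fitS@coefficients), c(0, 1), tolerance = 1e-9)

  # response independent of features: small |r|, matches oracle
  set.seed(99)
  tbl$noise <- rnorm(30)
  fitI <- mlrFit(tbl, c("rhc", "ph"), "noise")
  expect_lt(abs(fitI@pearsonR), 0.6)
  expect_equal(unname(fitI@coefficients),
               mlrOracle(tbl[, c("rhc", "ph")], tbl$noise), tolerance = 1e-9)
})

test_that("MLR guards against degenerate designs", {
  tbl <- data.frame(a = 1:10, b = rep(2, 10), y = rnorm(10))
  expect_error(mlrFit(tbl, c("a", "b"), "y"), "constant feature")
  tbl2 <- data.frame(a = 1:10 + 0.0, y = rnorm(10))
  tbl2$dup <- 2 * tbl2$a
  expect_warning(fit <- mlrFit(tbl2, c("a", "dup"), "y"), "collinear")
  expect_error(mlrFit(tbl2[1:2, ], c("a", "dup"), "y"), "more samples")
})

test_that("regression accuracy rises as trait noise falls", {
  set.seed(7)
  rFor <- function(sigma) {
    mean(vapply(1:30, function(i) {
      x1 <- runif(25); x2 <- runif(25)
      y <- 1 + 2 * x1 - x2 + rnorm(25, 0, sigma)
      mlrFit(data.frame(x1 = x1, x2 = x2, y = y), c("x1", "x2"), "y")@pearsonR
    }, numeric(1)))
  }
  expect_gt(rFor(0.1), rFor(1))
})

test_that("the standard trait combinations are exposed", {
  adm <- defaultFeatureSets("adm")
  expect_length(adm, 6)
  expect_equal(adm$shape_ph, c("gpar", "par", "ph"))
  k <- defaultFeatureSets("k")
  expect_length(k, 3)
  expect_equal(k$vertical, c("fit_a", "fit_b"))
})
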