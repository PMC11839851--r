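test_that("interval determination matches the hand-worked example", {
  s <- c(0.1, 0.2, 0.3, 0.4, 0.45, 0.55, 0.6, 0.7, 0.8, 0.9)
  iv <- determineInterval(s, 0.4)
  expect_equal(iv@nBelow, 2L)
  expect_equal(iv@nAbove, 2L)
  expect_equal(iv@lower, 0.35)
  expect_equal(iv@upper, 0.65)
  expect_equal(observedProportion(s, iv), 0.4)
})

test_that("degenerate and full-inclusion limits behave", {
  set.seed(4)
  s <- runif(40, 0, 1)
  iv0 <- determineInterval(s, 1e-4)          # k rounds to zero
  expect_equal(iv0@nBelow + iv0@nAbove, 0L)
  expect_true(all(classifyCertainty(s, iv0) == "CERTAIN"))
  expect_equal(coverage(iv0), 0)
  # full inclusion: equal-sided selection takes min(k, side size) per
  # side, so a balanced set is fully inconclusive at target 1 and an
  # unbalanced set keeps its surplus extremes certain
  sb <- c(sort(runif(20, 0, 0.5)), sort(runif(20, 0.500001, 1)))
  ivb <- determineInterval(sb, 1)
  expect_true(all(classifyCertainty(sb, ivb) == "INCONCLUSIVE"))
  iv1 <- suppressWarnings(determineInterval(s, 1))
  kB <- min(sum(s <= 0.5), floor(length(s) / 2 + 0.5))
  kA <- min(sum(s > 0.5), floor(length(s) / 2 + 0.5))
  expect_equal(sum(classifyCertainty(s, iv1) == "INCONCLUSIVE"), kB + kA)
  expect_error(determineInterval(numeric(0), 0.1), "empty")
  expect_error(determineInterval(s, 0), "targetProportion")
})

test_that("a lopsided sigmoid set clips with a warning", {
  s <- c(0.1, 0.2, 0.6, 0.61, 0.62, 0.7, 0.8, 0.9, 0.95, 0.99)
  expect_warning(iv <- determineInterval(s, 0.8), "available")
  expect_true(iv@clipped)
  expect_equal(iv@nBelow, 2L)  # the whole below side
  expect_equal(iv@lower, 0.1)  # distribution extreme
})

test_that("selection agrees with the exhaustive counting oracle", {
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(5:50, 1)
    s <- runif(n)
    p <- sample(seq(0.05, 0.6, by = 0.05), 1)
    k <- floor(p * n / 2 + 0.5)
    if (k == 0 || k > sum(s <= 0.5) || k > sum(s > 0.5)) next
    iv <- determineInterval(s, p)
    flags <- classifyCertainty(s, iv) == "INCONCLUSIVE"
    expect_identical(flags, oracleSelect(s, k))
  }
})

test_that("self-application recovers exactly 2k cases at every grid point", {
  set.seed(13)
  s <- runif(400)
  grid <- buildIntervalGrid(s)
  expect_length(intervals(grid), 50)
  for (i in seq_along(intervals(grid))) {
    iv <- intervals(grid)[[i]]
    n <- sum(classifyCertainty(s, iv) == "INCONCLUSIVE")
    expect_equal(n, iv@nBelow + iv@nAbove)
    expect_equal(iv@nBelow, iv@nAbove)
    k <- floor(targetProportions(grid)[i] * 400 / 2 + 0.5)
    expect_equal(iv@nBelow, as.integer(k))
  }
})

test_that("grid intervals are nested and observed proportions monotone", {
  set.seed(29)
  s <- runif(300)
  test <- runif(500)
  grid <- buildIntervalGrid(s)
  ivs <- intervals(grid)
  obs <- numeric(50)
  prev <- NULL
  for (i in 1:50) {
    iv <- ivs[[i]]
    obs[i] <- observedProportion(test, iv)
    if (!is.null(prev) && prev@nBelow > 0 && iv@nBelow > 0) {
      expect_lte(iv@lower, prev@lower)
      expect_gte(iv@upper, prev@upper)
    }
    if (iv@nBelow > 0) prev <- iv
  }
  expect_true(all(diff(obs) >= 0))
})

test_that("membership uses inclusive bounds and handles the 0.5 convention", {
  iv <- inconclusiveInterval(0.35, 0.65, 0.5)
  expect_equal(classifyCertainty(c(0.3, 0.4, 0.5, 0.66), iv),
               c("CERTAIN", "INCONCLUSIVE", "INCONCLUSIVE", "CERTAIN"))
  expect_equal(classifyCertainty(0.35, iv), "INCONCLUSIVE")  # s == lower
  expect_equal(classifyCertainty(0.65, iv), "INCONCLUSIVE")  # s == upper
  # sigmoids exactly at 0.5 count as the "below" side when selecting
  s <- c(0.5, 0.4, 0.6, 0.7)
  iv2 <- determineInterval(s, 0.5)
  expect_equal(iv2@nBelow, 1L)
  expect_equal(classifyCertainty(0.5, iv2), "INCONCLUSIVE")
})

test_that("interval coverage reproduces published-range arithmetic", {
  expect_equal(coverage(inconclusiveInterval(0.036, 0.985)), 94.9)
  expect_equal(coverage(inconclusiveInterval(0.163, 0.927)), 76.4)
  expect_equal(coverage(inconclusiveInterval(0, 1)), 100)
})
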