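test_that("balanced accuracy follows its definition and edge rules", {
  expect_equal(balancedAccuracy(list(tp = 8, fn = 2, tn = 6, fp = 4)), 70)
  perfect <- balancedAccuracy(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect, 100)
  allPos <- balancedAccuracy(rep(1, 10), c(rep(1, 6), rep(0, 4)))
  expect_equal(allPos, 50)
  # a stratum missing one class is undefined, never imputed
  expect_true(is.na(balancedAccuracy(c(1, 1), c(1, 1))))
  # invariant under duplicating every case
  pred <- c(1, 0, 1, 1, 0)
  truth <- c(1, 0, 0, 1, 1)
  expect_equal(balancedAccuracy(pred, truth),
               balancedAccuracy(rep(pred, 2), rep(truth, 2)))
})

test_that("certainty curve matches hand enumeration on a toy set", {
  sig <- c(0.05, 0.1, 0.45, 0.48, 0.52, 0.9, 0.95, 0.6, 0.02, 0.97)
  truth <- c(0, 0, 0, 1, 1, 1, 1, 1, 0, 1)
  grid <- new("IntervalGrid", targets = c(0.1, 0.3, 0.9),
              intervals = list(
                inconclusiveInterval(0.46, 0.54, 0.1),
                inconclusiveInterval(0.40, 0.70, 0.3),
                inconclusiveInterval(0.05, 0.95, 0.9)))
  curve <- certaintyCurve(sig, truth, grid)
  # interval 1: cases 0.48, 0.52 inconclusive -> observed 0.2;
  #   certain: pred (0,0,0,1,1,1,0,1) truth (0,0,0,1,1,1,0,1) -> BA 100
  expect_equal(curve$observed, c(0.2, 0.4, 0.8))
  expect_equal(curve$baCertain[1], 100)
  # interval 2 adds 0.45 and 0.6: certain truth (0,0,1,1,1,0,1), all right
  expect_equal(curve$baCertain[2], 100)
  # interval 3 keeps only 0.02 and 0.97 certain -> BA 100; inconclusive
  #   stratum: preds (0,0,0,0,1,1,1,1) truths (0,0,0,1,1,1,1,1):
  #   sens 4/5... hand check below
  tp <- 4; fn <- 1; tn <- 3; fp <- 0
  expect_equal(curve$baInconclusive[3],
               100 * (tp / (tp + fn) + tn / (tn + fp)) / 2)
})

test_that("certainty AUC reproduces closed-form trapezoids", {
  flat <- data.frame(observed = c(0.002, 0.05, 0.10),
                     baCertain = c(100, 100, 100))
  expect_equal(certaintyAUC(flat), 100)
  flat90 <- transform(flat, baCertain = 90)
  expect_equal(certaintyAUC(flat90), 90)
  two <- data.frame(observed = c(0.002, 0.10), baCertain = c(90, 100))
  expect_equal(certaintyAUC(two), 95)
  # inserting a collinear point changes nothing
  three <- data.frame(observed = c(0.002, 0.051, 0.10),
                      baCertain = c(90, 95, 100))
  expect_equal(certaintyAUC(three), certaintyAUC(two))
  # NA points are gaps, not zeros
  gap <- data.frame(observed = c(0.002, 0.05, 0.10),
                    baCertain = c(90, NA, 100))
  expect_equal(certaintyAUC(gap), 95)
  expect_error(certaintyAUC(data.frame(observed = 0.05, baCertain = 90)),
               "two curve points")
})

test_that("regression through the origin recovers exact slopes", {
  x <- seq(0.002, 0.1, by = 0.002)
  expect_equal(regressionThroughOrigin(x, x), 1)
  expect_equal(regressionThroughOrigin(x, 1.5 * x), 1.5)
  expect_equal(regressionThroughOrigin(x, 0 * x), 0)
  expect_error(regressionThroughOrigin(rep(0, 5), rep(1, 5)), "zero")
  # least-squares property on noisy data: matches lm without intercept
  set.seed(6)
  y <- 1.2 * x + rnorm(50, sd = 0.01)
  expect_equal(regressionThroughOrigin(x, y),
               unname(coef(lm(y ~ x + 0))["x"]))
})

test_that("distance by consistency summarizes the two reader groups", {
  sig <- c(0.9, 0.1, 0.55)
  votes <- rbind(c(1, 1, 1), c(0, 0, 0), c(1, 0, 1))
  out <- distanceByConsistency(sig, votes)
  expect_equal(out$mean[out$group == "consistent"], 0.4)
  expect_equal(out$mean[out$group == "discrepant"], 0.05)
  # group membership invariant under vote-order permutation
  out2 <- distanceByConsistency(sig, votes[, c(3, 1, 2)])
  expect_equal(out, out2)
  # all sigmoids at the threshold: both means zero
  out3 <- distanceByConsistency(rep(0.5, 3), votes)
  expect_equal(out3$mean, c(0, 0))
  # an empty group is absent, not fabricated
  out4 <- distanceByConsistency(c(0.9, 0.1), votes[1:2, ])
  expect_equal(out4$group, "consistent")
})

test_that("the corrected resampled t-test matches its closed form", {
  d <- 1:10
  h <- nadeauBengioTest(d, rep(0, 10), rho = 1 / 3)
  expect_equal(unname(h$statistic),
               mean(d) / sqrt((1 / 10 + 1 / 3) * var(d)))
  expect_equal(unname(h$statistic), 2.759, tolerance = 1e-3)
  expect_equal(unname(h$parameter), 9)
  expect_equal(h$p.value, 2 * pt(-abs(unname(h$statistic)), 9))
  # rho -> 0 recovers the classical paired t statistic
  x <- c(5, 7, 3, 8, 6)
  y <- c(4, 9, 2, 8, 5)
  hsmall <- nadeauBengioTest(x, y, rho = 1e-12)
  classical <- t.test(x, y, paired = TRUE)
  expect_equal(unname(hsmall$statistic), unname(classical$statistic),
               tolerance = 1e-5)
  # the correction can only weaken evidence
  h13 <- nadeauBengioTest(x, y, rho = 1 / 3)
  expect_gte(h13$p.value, classical$p.value)
  # antisymmetry
  expect_equal(unname(nadeauBengioTest(y, x, rho = 1 / 3)$statistic),
               -unname(h13$statistic))
  # degenerate inputs
  h0 <- nadeauBengioTest(rep(0, 5), rep(0, 5))
  expect_equal(unname(h0$statistic), 0)
  expect_equal(h0$p.value, 1)
  expect_warning(hz <- nadeauBengioTest(rep(2, 5), rep(0, 5)), "zero variance")
  expect_equal(hz$p.value, 0)
})
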