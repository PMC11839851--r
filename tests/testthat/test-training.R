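test_that("patient-level splits have the right sizes and no leakage", {
  ids <- sprintf("s%04d", 1:1740)
  sp <- makeSplits(ids, K = 2, seed = 3)
  for (k in 1:2) {
    sk <- sp[sp$realization == k, ]
    counts <- table(sk$subset)
    expect_equal(unname(c(counts)), c(1044, 348, 348))
    # image-level counts are 12x the scan-level counts
    expect_equal(unname(c(counts)) * 12, c(12528, 4176, 4176))
    # partition: every scan in exactly one subset
    expect_setequal(sk$scan_id, ids)
    expect_equal(anyDuplicated(sk$scan_id), 0)
    expect_length(intersect(splitScans(sp, k, "TRAIN"),
                            splitScans(sp, k, "TEST")), 0)
    expect_length(intersect(splitScans(sp, k, "TRAIN"),
                            splitScans(sp, k, "VAL")), 0)
  }
  expect_identical(makeSplits(ids, K = 2, seed = 3), sp)
  expect_false(identical(splitScans(sp, 1, "TRAIN"),
                         splitScans(sp, 2, "TRAIN")))
  expect_error(makeSplits(c("a", "b"), K = 1), "fewer scans")
})

test_that("different methods start from identical weights", {
  spec <- archSpec(32, 2 / 64)
  a <- buildNetwork(spec, seed = 5)
  b <- buildNetwork(spec, seed = 5)
  expect_identical(a@env$params, b@env$params)
})

test_that("loss definitions behave at their fixed points", {
  lg <- SpectCertainty:::.lossGrad
  # AVT/MSE: outputs equal to targets give exactly zero loss
  z <- stats::qlogis(c(1 / 3, 2 / 3, 0.5))
  out <- lg(z, c(1 / 3, 2 / 3, 0.5), "mse")
  expect_equal(out$value, 0)
  expect_equal(out$dz, rep(0, 3))
  # BCE gradient is (sigmoid - target) / batch
  z <- c(-2, 0, 3)
  y <- c(0, 1, 1)
  out <- lg(z, y, "bce")
  expect_equal(out$dz, (stats::plogis(z) - y) / 3)
  expect_equal(out$value,
               -mean(y * log(stats::plogis(z)) +
                       (1 - y) * log(1 - stats::plogis(z))))
})

test_that("training separates a clean cohort and the loss decreases", {
  # boundary band removed: a thresholded striatal mean already separates
  # the classes, so the network must reach perfect training accuracy
  sevModel <- severityModel(normalMass = 0.5, reducedMass = 0.5,
                            bandMass = 0)
  coh <- generateCohort(cohortConfig(nScans = 30, imageSize = 32,
                                     pixelSizeMm = 6,
                                     severity = sevModel, seed = 19))
  sp <- makeSplits(scanInfo(coh)$scan_id, K = 1, seed = 2)
  cfg <- trainingConfig("MVT", epochs = 6, batchSize = 32, seed = 4)
  net <- trainNetwork(coh, sp, cfg, archSpec(32, 0.25))
  expect_lt(net@log$loss[6], net@log$loss[1])
  pred <- predictSigmoid(net, coh, splitScans(sp, 1, "TRAIN"))
  truth <- trueClasses(coh)[match(pred$scan_id, scanInfo(coh)$scan_id)]
  expect_equal(balancedAccuracy(pred$prediction, truth), 100)
})

test_that("random-vote targets are redrawn across presentations", {
  votes <- rbind(c(1, 1, 0))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(77)
  draws <- replicate(300, randomVote(votes))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  se <- sqrt(2 / 3 * 1 / 3 / 300)
  expect_lt(abs(mean(draws) - 2 / 3), 3 * se)
  expect_gt(length(unique(draws)), 1)
})

test_that("prediction applies the 0.5 decision rule and is repeatable", {
  coh <- tinyCohort(nScans = 10, imageSize = 32)
  sp <- makeSplits(scanInfo(coh)$scan_id, K = 1, seed = 1)
  cfg <- trainingConfig("AVT", epochs = 1, batchSize = 32, seed = 9)
  net <- trainNetwork(coh, sp, cfg, archSpec(32, 0.25))
  p1 <- predictSigmoid(net, coh)
  p2 <- predictSigmoid(net, coh)
  expect_identical(p1$sigmoid, p2$sigmoid)
  expect_equal(p1$prediction, as.integer(p1$sigmoid > 0.5))
  # boundary convention: sigmoid exactly 0.5 is "normal"
  expect_equal(as.integer(0.5 > 0.5), 0L)
  expect_equal(nrow(p1), nInstances(coh))
})

test_that("training-method preconditions are enforced", {
  coh <- tinyCohort(nScans = 10, imageSize = 32)
  # single-reader cohort: RVT and AVT must refuse
  coh1 <- coh
  coh1@votes <- coh@votes[, 1, drop = FALSE]
  sp <- makeSplits(scanInfo(coh)$scan_id, K = 1, seed = 1)
  expect_error(trainNetwork(coh1, sp, trainingConfig("RVT", epochs = 1),
                            archSpec(32, 0.25)), "2 readers")
  expect_error(trainNetwork(coh1, sp, trainingConfig("AVT", epochs = 1),
                            archSpec(32, 0.25)), "2 readers")
  expect_error(trainNetwork(coh, sp, trainingConfig("MVT", epochs = 1),
                            archSpec(64, 0.25)), "size")
})
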