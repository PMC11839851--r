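test_that("fidelity-mode parameter accounting matches the reference layer by layer", {
  acct <- parameterAccount(archSpec(224, 1))
  per <- setNames(acct$perLayer$params, acct$perLayer$layer)
  expect_equal(per[["stem.conv"]], 3136)
  expect_equal(per[["stem.bn"]], 128)
  expect_equal(unname(per[c("s1.b1", "s1.b2")]), c(73984, 73984))
  expect_equal(unname(per[c("s2.b1", "s2.b2")]), c(230144, 295424))
  expect_equal(unname(per[c("s3.b1", "s3.b2")]), c(919040, 1180672))
  expect_equal(unname(per[c("s4.b1", "s4.b2")]), c(3673088, 4720640))
  expect_equal(per[["fc"]], 513)
  expect_equal(acct$total, 11170753)
  expect_equal(acct$trainable, 11170753)
})

test_that("desk-mode accounting agrees with brute-force enumeration of built weights", {
  spec <- archSpec(64, 0.25)
  net <- buildNetwork(spec, seed = 4)
  enumerated <- sum(vapply(net@env$params, length, numeric(1)))
  expect_equal(parameterAccount(spec)$total, enumerated)
  # and for an odd width multiplier
  spec2 <- archSpec(64, 0.125)
  expect_equal(parameterAccount(spec2)$total,
               sum(vapply(buildNetwork(spec2, 1)@env$params, length,
                          numeric(1))))
})

test_that("weight initialization is deterministic in the seed", {
  a <- buildNetwork(archSpec(64, 0.25), seed = 9)
  b <- buildNetwork(archSpec(64, 0.25), seed = 9)
  expect_identical(a@env$params, b@env$params)
  c <- buildNetwork(archSpec(64, 0.25), seed = 10)
  expect_false(identical(a@env$params$stem.conv, c@env$params$stem.conv))
})

test_that("activation shapes in fidelity mode match the reference table", {
  sh <- traceShapes(archSpec(224, 1))
  get <- function(l) unlist(sh[sh$layer == l, c("channels", "height", "width")])
  expect_equal(unname(get("stem.conv")), c(64, 112, 112))
  expect_equal(unname(get("stem.pool")), c(64, 56, 56))
  expect_equal(unname(get("s2.b1")), c(128, 28, 28))
  expect_equal(unname(get("s4.b2")), c(512, 7, 7))
})

test_that("forward pass yields sigmoids strictly inside (0, 1)", {
  net <- buildNetwork(archSpec(32, 2 / 64), seed = 2)
  set.seed(5)
  x <- array(runif(32 * 32 * 4), c(32, 32, 1, 4))
  z <- SpectCertainty:::.nnForward(net, x)$z
  sig <- stats::plogis(z)
  expect_true(all(sig > 0 & sig < 1))
  # zeroed output layer pins the sigmoid at exactly 0.5
  net@env$params$fc.W[] <- 0
  net@env$params$fc.b <- 0
  z0 <- SpectCertainty:::.nnForward(net, x)$z
  expect_equal(stats::plogis(z0), rep(0.5, 4))
})

test_that("wrong input channel count raises an explicit shape error", {
  net <- buildNetwork(archSpec(32, 2 / 64), seed = 2)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  expect_error(SpectCertainty:::.nnForward(net, x), "single input channel")
})

test_that("storage accounting uses 4 bytes per value", {
  expect_equal(parameterAccount(archSpec(224, 1))$paramMB, 44.68,
               tolerance = 1e-3)
  expect_equal(inputStorageMB(archSpec(224, 1), 64), 12.85,
               tolerance = 1e-3)
})

test_that("bicubic resize honours its contracts", {
  expect_equal(resizeBicubic(matrix(3.7, 8, 8), 24),
               matrix(3.7, 24, 24), tolerance = 1e-6)
  out <- resizeBicubic(matrix(rnorm(64 * 64), 64), 224)
  expect_equal(dim(out), c(224, 224))
  expect_error(resizeBicubic(matrix(1, 4, 4), -1), "positive")
  # round trip on a smooth band-limited image
  tpl <- slabTemplate(phantomParams(severity = 0.3, noiseSd = 0), 64)
  sm <- SpectCertainty:::.gaussianBlur(tpl, 12, 3)
  rt <- resizeBicubic(resizeBicubic(sm, 224), 64)
  mae <- mean(abs(rt - sm))
  expect_lt(mae, 0.02 * diff(range(sm)))
})
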