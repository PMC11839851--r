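test_that("phantom generation is a pure function of its seed", {
  p <- phantomParams(severity = 0.5, noiseSd = 3)
  a <- generatePhantom(p, "ASC", 12, seed = 99)
  b <- generatePhantom(p, "ASC", 12, seed = 99)
  expect_identical(a, b)
  c <- generatePhantom(p, "ASC", 12, seed = 100)
  expect_false(identical(a, c))
})

test_that("striatal signal decreases strictly with severity before noise", {
  roi <- striatalROI(64)
  means <- vapply(seq(0, 1, by = 0.05), function(s) {
    mean(slabTemplate(phantomParams(severity = s, noiseSd = 0), 64)[roi])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("template reproduces the configured striatal contrast", {
  p <- phantomParams(severity = 0, noiseSd = 0, striatalContrast = 4)
  tpl <- slabTemplate(p, 64)
  ratio <- mean(tpl[striatalROI(64)]) / mean(tpl[backgroundROI(64)])
  expect_equal(ratio, 4, tolerance = 0.01)
  # and for a different contrast setting
  p2 <- phantomParams(severity = 0, noiseSd = 0, striatalContrast = 2.5)
  tpl2 <- slabTemplate(p2, 64)
  ratio2 <- mean(tpl2[striatalROI(64)]) / mean(tpl2[backgroundROI(64)])
  expect_equal(ratio2, 2.5, tolerance = 0.01)
})

test_that("parameter validation rejects invalid inputs", {
  expect_error(phantomParams(severity = 1.2), "severity")
  expect_error(phantomParams(striatalContrast = 0.9), "striatalContrast")
  expect_error(phantomParams(noiseSd = -1), "noiseSd")
  expect_error(generatePhantom(phantomParams(), smoothingFwhmMm = 11),
               "smoothingFwhmMm")
})

test_that("smoothing and variants behave as documented", {
  p <- phantomParams(severity = 0.2, noiseSd = 0)
  sharp <- generatePhantom(p, "ASC", 0, seed = 1)
  smooth <- generatePhantom(p, "ASC", 18, seed = 1)
  # smoothing shrinks the peak and preserves non-negativity
  expect_lt(max(smooth), max(sharp))
  expect_gte(min(smooth), 0)
  # NOASC raises the background and compresses contrast
  asc <- slabTemplate(p, 64, "ASC")
  noasc <- slabTemplate(p, 64, "NOASC")
  bg <- backgroundROI(64)
  expect_gt(mean(noasc[bg]), mean(asc[bg]))
  expect_lt(mean(noasc[striatalROI(64)]) / mean(noasc[bg]),
            mean(asc[striatalROI(64)]) / mean(asc[bg]))
})
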