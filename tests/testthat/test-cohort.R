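test_that("every scan carries exactly 12 instances (2 variants x 6 smoothings)", {
  coh <- tinyCohort(nScans = 10)
  expect_equal(nScans(coh), 10)
  expect_equal(nInstances(coh), 120)
  inst <- instanceInfo(coh)
  perScan <- table(inst$scan_id)
  expect_true(all(perScan == 12))
  perVariant <- table(inst$scan_id, inst$variant)
  expect_true(all(perVariant == 6))
  expect_setequal(unique(inst$smoothing_fwhm_mm), c(0, 10, 12, 14, 16, 18))
  expect_equal(nrow(readerVotes(coh)), 10)
})

test_that("cohort generation is fully reproducible from its seed", {
  a <- tinyCohort(nScans = 10, seed = 42)
  b <- tinyCohort(nScans = 10, seed = 42)
  expect_identical(severities(a), severities(b))
  expect_identical(readerVotes(a), readerVotes(b))
  expect_identical(a@images, b@images)
})

test_that("cohort validation rejects undersized requests", {
  expect_error(cohortConfig(nScans = 5), "nScans")
  expect_error(generateOodCohort(cohortConfig(nScans = 20)), "IN_DIST")
  expect_error(
    generateCohort(cohortConfig(nScans = 20, oodProfile = "PPMI_LIKE")),
    "generateOodCohort")
})

test_that("out-of-distribution cohorts have one instance and shifted physics", {
  cfg <- function(p) cohortConfig(nScans = 40, imageSize = 32,
                                  pixelSizeMm = 6, oodProfile = p,
                                  seed = 77)
  mph <- generateOodCohort(cfg("MPH_LIKE"))
  expect_equal(nInstances(mph), 40)
  expect_equal(nScans(mph), 40)
  expect_equal(ncol(readerVotes(mph)), 1)
  # profile ordering by construction: MPH-like sharper and cleaner
  pm <- SpectCertainty:::.profileParams(cfg("MPH_LIKE"))
  pi <- SpectCertainty:::.profileParams(cfg("IN_DIST"))
  pp <- SpectCertainty:::.profileParams(cfg("PPMI_LIKE"))
  expect_lt(pm$noiseSd, pi$noiseSd)
  expect_gt(pm$striatalContrast, pi$striatalContrast)
  expect_lt(pm$psfFwhmMm, pi$psfFwhmMm)
  expect_gt(pp$psfFwhmMm, pi$psfFwhmMm)
  # measured contrast summary strictly higher for MPH-like
  roi <- striatalROI(32, 6); bg <- backgroundROI(32, 6)
  ind <- generateCohort(cfg("IN_DIST"))
  ratioOf <- function(coh, idx) {
    mean(vapply(idx, function(i) {
      img <- slabImage(coh, i)
      mean(img[roi]) / mean(img[bg])
    }, numeric(1)))
  }
  lowSev <- scanInfo(ind)$scan_id[severities(ind) < 0.2]
  ii <- instanceInfo(ind)
  idxInd <- which(ii$scan_id %in% lowSev & ii$variant == "ASC" &
                    ii$smoothing_fwhm_mm == 0)
  idxMph <- which(instanceInfo(mph)$scan_id %in%
                    scanInfo(mph)$scan_id[severities(mph) < 0.2])
  expect_gt(ratioOf(mph, idxMph), ratioOf(ind, idxInd))
})

test_that("out-of-distribution prevalence matches its target", {
  cfg <- cohortConfig(nScans = 300, imageSize = 32, pixelSizeMm = 6,
                      oodProfile = "PPMI_LIKE", seed = 9)
  coh <- generateOodCohort(cfg)
  phat <- mean(trueClasses(coh))
  # binomial 95% CI around the configured 0.679
  expect_lt(abs(phat - 0.679), 1.96 * sqrt(0.679 * 0.321 / 300))
})

test_that("cohorts round-trip through NIfTI + CSV sidecars", {
  coh <- tinyCohort(nScans = 10, imageSize = 16)
  dir <- file.path(tempdir(), "cohort-rt")
  writeCohort(coh, dir)
  back <- readCohort(dir)
  expect_equal(nScans(back), nScans(coh))
  expect_equal(readerVotes(back), readerVotes(coh))
  expect_equal(back@images, coh@images, tolerance = 1e-6)
  expect_equal(scanInfo(back)$severity, scanInfo(coh)$severity,
               tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
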