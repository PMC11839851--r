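# Cohort generation ------------------------------------------------------

#' Severity mixture of the synthetic cohort
#'
#' Latent disease severity is drawn from a three-component mixture: a
#' clearly-normal Beta component, a clearly-reduced (mirrored) Beta
#' component, and a thin uniform "boundary band" straddling the class
#' boundary.  The band carries the borderline scans on which the
#' simulated readers disagree; its mass (default 8\%) together with the
#' reader model reproduces the published vote-pattern frequencies.
#'
#' @param normalMass,reducedMass,bandMass mixture weights (sum to 1).
#' @param bandLo,bandHi bounds of the uniform boundary band.
#' @param normalMax upper end of the normal component's support.
#' @param reducedMin lower end of the reduced component's support.
#' @param shape1,shape2 Beta shape parameters of the outer components.
#' @return a list of class `SeverityModel`.
#' @export
severityModel <- function(normalMass, reducedMass, bandMass,
                          bandLo = 0.44, bandHi = 0.58,
                          normalMax = 0.40, reducedMin = 0.60,
                          shape1 = 1.8, shape2 = 4.5) {
  w <- c(normalMass, reducedMass, bandMass)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("mixture weights must be non-negative and sum to 1")
  if (!(bandLo < bandHi && normalMax <= bandLo && bandHi <= reducedMin))
    stop("components must be ordered: normal | band | reduced")
  structure(list(normalMass = normalMass, reducedMass = reducedMass,
                 bandMass = bandMass, bandLo = bandLo, bandHi = bandHi,
                 normalMax = normalMax, reducedMin = reducedMin,
                 shape1 = shape1, shape2 = shape2),
            class = "SeverityModel")
}

#' @rdname severityModel
#' @details `defaultSeverityModel()` carries the in-distribution
#'   defaults calibrated against the published vote-pattern table;
#'   `oodSeverityModel(prevalence)` keeps the band but rebalances the
#'   outer components to a prescribed reduced-class prevalence.
#' @export
defaultSeverityModel <- function() {
  severityModel(normalMass = 0.47839, reducedMass = 0.44161,
                bandMass = 0.08)
}

#' @rdname severityModel
#' @param prevalence desired probability that severity exceeds 0.5.
#' @export
oodSeverityModel <- function(prevalence) {
  stopIfNot01(prevalence, "prevalence")
  m <- defaultSeverityModel()
  bandAbove <- m$bandMass * (m$bandHi - 0.5) / (m$bandHi - m$bandLo)
  reduced <- prevalence - bandAbove
  if (reduced < 0 || reduced > 1 - m$bandMass)
    stop("prevalence incompatible with the boundary-band mass")
  severityModel(normalMass = 1 - m$bandMass - reduced,
                reducedMass = reduced, bandMass = m$bandMass)
}

#' @rdname severityModel
#' @param model a `SeverityModel`.
#' @return `severityDensity` returns the mixture density as a function.
#' @export
severityDensity <- function(model = defaultSeverityModel()) {
  force(model)
  function(s) {
    dn <- ifelse(s >= 0 & s <= model$normalMax,
                 stats::dbeta(s / model$normalMax, model$shape1,
                              model$shape2) / model$normalMax, 0)
    dr <- ifelse(s >= model$reducedMin & s <= 1,
                 stats::dbeta((1 - s) / (1 - model$reducedMin),
                              model$shape1, model$shape2) /
                   (1 - model$reducedMin), 0)
    db <- ifelse(s >= model$bandLo & s <= model$bandHi,
                 1 / (model$bandHi - model$bandLo), 0)
    model$normalMass * dn + model$reducedMass * dr + model$bandMass * db
  }
}

#' Draw latent severities from the mixture
#'
#' @param n number of scans.
#' @param model a [severityModel()].
#' @param seed integer seed.
#' @return numeric vector in `[0, 1]`.
#' @export
sampleSeverities <- function(n, model = defaultSeverityModel(), seed = 1) {
  withSeed(seed, {
    comp <- sample.int(3, n, replace = TRUE,
                       prob = c(model$normalMass, model$bandMass,
                                model$reducedMass))
    s <- numeric(n)
    idx <- comp == 1
    s[idx] <- model$normalMax * rbeta(sum(idx), model$shape1, model$shape2)
    idx <- comp == 2
    s[idx] <- runif(sum(idx), model$bandLo, model$bandHi)
    idx <- comp == 3
    s[idx] <- 1 - (1 - model$reducedMin) *
      rbeta(sum(idx), model$shape1, model$shape2)
    s
  })
}

.oodProfiles <- c("IN_DIST", "PPMI_LIKE", "MPH_LIKE")

#' Cohort configuration
#'
#' Bundles every knob of the synthetic-cohort generator.  The defaults
#' define the study conditions: 3 mm pixels on a 64 x 64 grid, striatal
#' contrast 4, 5\% background noise, a 10 mm scanner point-spread, the
#' calibrated severity mixture and three-reader panel, and the
#' augmentation scheme of 2 reconstruction variants x 6 smoothing
#' levels.  The out-of-distribution profiles shift resolution, noise
#' and class prevalence: `PPMI_LIKE` has lower resolution (13 mm PSF),
#' slightly more noise and 67.9\% prevalence; `MPH_LIKE` has better
#' resolution (6.5 mm PSF), higher contrast, half the noise and 51.1\%
#' prevalence.
#'
#' @param nScans number of scans (>= 10).
#' @param imageSize image side length in pixels.
#' @param pixelSizeMm pixel size in mm.
#' @param backgroundLevel,striatalContrast,noiseSd,psfFwhmMm see
#'   [phantomParams()].
#' @param asymmetryMean mean of the per-scan uniform asymmetry draw.
#' @param severity a [severityModel()].
#' @param readers a [readerModel()].
#' @param votePatternTargets published calibration targets for the
#'   proportions of scans reduced by 0/1/2/3 readers.
#' @param oodProfile `"IN_DIST"`, `"PPMI_LIKE"` or `"MPH_LIKE"`.
#' @param seed master seed; every random quantity of the cohort derives
#'   from it.
#' @return a list of class `CohortConfig`.
#' @export
cohortConfig <- function(nScans = 200, imageSize = 64, pixelSizeMm = 3,
                         backgroundLevel = 50, striatalContrast = 4,
                         noiseSd = 2.5, psfFwhmMm = 10,
                         asymmetryMean = 0.3,
                         severity = defaultSeverityModel(),
                         readers = defaultReaderModel(),
                         votePatternTargets = c(reduced_by_0 = 0.491,
                                                reduced_by_1 = 0.028,
                                                reduced_by_2 = 0.020,
                                                reduced_by_3 = 0.461),
                         oodProfile = "IN_DIST", seed = 1) {
  if (nScans < 10) stop("nScans must be at least 10")
  oodProfile <- match.arg(oodProfile, .oodProfiles)
  structure(as.list(environment()), class = "CohortConfig")
}

# Profile-specific acquisition parameters.
.profileParams <- function(config) {
  p <- list(psfFwhmMm = config$psfFwhmMm, noiseSd = config$noiseSd,
            striatalContrast = config$striatalContrast,
            prevalence = NA_real_)
  switch(config$oodProfile,
    IN_DIST = p,
    PPMI_LIKE = {
      p$psfFwhmMm <- config$psfFwhmMm * 1.3
      p$noiseSd <- config$noiseSd * 1.2
      p$prevalence <- 0.679
      p
    },
    MPH_LIKE = {
      p$psfFwhmMm <- config$psfFwhmMm * 0.65
      p$noiseSd <- config$noiseSd * 0.5
      p$striatalContrast <- config$striatalContrast * 1.3
      p$prevalence <- 0.511
      p
    })
}

.renderScan <- function(config, prof, severity, asymmetry, scanSeed,
                        variants, fwhms) {
  params <- phantomParams(severity = severity, asymmetry = asymmetry,
                          backgroundLevel = config$backgroundLevel,
                          striatalContrast = prof$striatalContrast,
                          noiseSd = prof$noiseSd,
                          pixelSizeMm = config$pixelSizeMm,
                          psfFwhmMm = prof$psfFwhmMm)
  out <- vector("list", length(variants) * length(fwhms))
  i <- 0L
  for (v in seq_along(variants)) {
    # one noise realization per reconstruction variant; the smoothing
    # levels are post-hoc filters of the same reconstruction
    base <- slabTemplate(params, config$imageSize, variants[v])
    base <- .gaussianBlur(base, params$psfFwhmMm, params$pixelSizeMm)
    if (params$noiseSd > 0) {
      noise <- withSeed(deriveSeed(scanSeed, v),
                        rnorm(length(base), sd = params$noiseSd))
      base <- base + matrix(noise, nrow(base))
    }
    base <- pmax(base, 0)
    for (f in fwhms) {
      i <- i + 1L
      out[[i]] <- pmax(.gaussianBlur(base, f, params$pixelSizeMm), 0)
    }
  }
  out
}

#' Generate a synthetic in-distribution cohort
#'
#' Draws latent severities, simulates the three-reader panel and
#' renders all `2 * 6 = 12` augmentation instances per scan (ASC/NOASC
#' reconstruction x smoothing FWHM 0, 10, 12, 14, 16, 18 mm).  The
#' whole cohort is a pure function of `config$seed`.
#'
#' @param config a [cohortConfig()] with profile `"IN_DIST"`.
#' @return a [SlabCohort-class].
#' @examples
#' coh <- generateCohort(cohortConfig(nScans = 10, imageSize = 32))
#' nInstances(coh)  # 120
#' @export
generateCohort <- function(config = cohortConfig()) {
  if (config$oodProfile != "IN_DIST")
    stop("use generateOodCohort() for out-of-distribution profiles")
  prof <- .profileParams(config)
  n <- config$nScans
  sev <- sampleSeverities(n, config$severity, deriveSeed(config$seed, 1))
  votes <- simulateReaderPanel(sev, config$readers,
                               deriveSeed(config$seed, 2))
  asym <- withSeed(deriveSeed(config$seed, 3),
                   runif(n, 0, 2 * config$asymmetryMean))
  variants <- c("ASC", "NOASC")
  fwhms <- .smoothingLevels
  scanIds <- sprintf("scan%05d", seq_len(n))
  rownames(votes) <- scanIds

  m <- length(variants) * length(fwhms)
  images <- array(0, c(config$imageSize, config$imageSize, n * m))
  inst <- data.frame(
    instance_id = character(n * m), scan_id = character(n * m),
    variant = character(n * m), smoothing_fwhm_mm = numeric(n * m),
    stringsAsFactors = FALSE)
  k <- 0L
  for (i in seq_len(n)) {
    imgs <- .renderScan(config, prof, sev[i], asym[i],
                        deriveSeed(config$seed, 100L + i), variants, fwhms)
    j <- 0L
    for (v in variants) for (f in fwhms) {
      k <- k + 1L
      j <- j + 1L
      images[, , k] <- imgs[[j]]
      inst$instance_id[k] <- sprintf("%s_%s_f%02d", scanIds[i], v, f)
      inst$scan_id[k] <- scanIds[i]
      inst$variant[k] <- v
      inst$smoothing_fwhm_mm[k] <- f
    }
  }
  scans <- data.frame(scan_id = scanIds, severity = sev,
                      true_class = as.integer(sev > 0.5),
                      stringsAsFactors = FALSE)
  new("SlabCohort", images = images, instances = inst, scans = scans,
      votes = votes, profile = "IN_DIST", config = unclass(config))
}

#' Generate an out-of-distribution test cohort
#'
#' One unsmoothed ASC instance per scan and a single reference label
#' (the generator truth), emulating external test sets whose
#' acquisition characteristics and class prevalence differ from the
#' development data.
#'
#' @param config a [cohortConfig()] with profile `"PPMI_LIKE"` or
#'   `"MPH_LIKE"`.
#' @return a [SlabCohort-class].
#' @export
generateOodCohort <- function(config) {
  if (config$oodProfile == "IN_DIST")
    stop("generateOodCohort() requires an out-of-distribution profile; ",
         "use generateCohort() for IN_DIST")
  prof <- .profileParams(config)
  n <- config$nScans
  sev <- sampleSeverities(n, oodSeverityModel(prof$prevalence),
                          deriveSeed(config$seed, 1))
  asym <- withSeed(deriveSeed(config$seed, 3),
                   runif(n, 0, 2 * config$asymmetryMean))
  scanIds <- sprintf("%s%05d", tolower(substr(config$oodProfile, 1, 4)),
                     seq_len(n))
  images <- array(0, c(config$imageSize, config$imageSize, n))
  for (i in seq_len(n)) {
    images[, , i] <- .renderScan(config, prof, sev[i], asym[i],
                                 deriveSeed(config$seed, 100L + i),
                                 "ASC", 0)[[1]]
  }
  inst <- data.frame(instance_id = paste0(scanIds, "_ASC_f00"),
                     scan_id = scanIds, variant = "ASC",
                     smoothing_fwhm_mm = 0, stringsAsFactors = FALSE)
  trueClass <- as.integer(sev > 0.5)
  votes <- matrix(trueClass, ncol = 1,
                  dimnames = list(scanIds, "reference"))
  scans <- data.frame(scan_id = scanIds, severity = sev,
                      true_class = trueClass, stringsAsFactors = FALSE)
  new("SlabCohort", images = images, instances = inst, scans = scans,
      votes = votes, profile = config$oodProfile,
      config = unclass(config))
}
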