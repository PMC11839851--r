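# End-to-end experiment: simulate -> split -> train x methods x K ->
# predict -> intervals -> evaluate ---------------------------------------

#' Experiment configuration
#'
#' Desk-scale defaults: a 200-scan development cohort of 64 x 64 slabs,
#' a width-0.25 network, K = 3 split realizations and all three
#' training methods.  `epochs = 12` is the shortest training length at
#' which hard-label training reaches the saturated-sigmoid regime on
#' this cohort that the reference 20-epoch protocol produces, while
#' keeping a full desk experiment in the minutes range on one CPU.
#'
#' @param nScans development-cohort size (scans).
#' @param oodScans size of each out-of-distribution test cohort.
#' @param imageSize slab side length in pixels.
#' @param widthMult network width multiplier.
#' @param K number of split realizations.
#' @param methods training methods to run.
#' @param epochs,batchSize,lr training hyperparameters.
#' @param gridTargets inconclusive-interval target proportions.
#' @param oodProfiles out-of-distribution profiles to generate.
#' @param seed master seed; every stage derives its own stream from it.
#' @return a list of class `ExperimentConfig`.
#' @export
experimentConfig <- function(nScans = 200, oodScans = 120, imageSize = 64,
                             widthMult = 0.25, K = 3,
                             methods = c("MVT", "RVT", "AVT"),
                             epochs = 12, batchSize = 64, lr = 1e-4,
                             gridTargets = (1:50) / 500,
                             oodProfiles = c("PPMI_LIKE", "MPH_LIKE"),
                             seed = 1) {
  methods <- match.arg(methods, c("MVT", "RVT", "AVT"),
                       several.ok = TRUE)
  structure(as.list(environment()), class = "ExperimentConfig")
}

#' Load an experiment configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the
#'   [experimentConfig()] arguments.
#' @return an `ExperimentConfig`.
#' @export
readExperimentConfig <- function(path) {
  do.call(experimentConfig, yaml::read_yaml(path))
}

# AUC with a constant-curve fallback: a curve with a single defined
# point (every interval lands the same observed proportion, e.g. a test
# subset without borderline cases) is a constant curve, whose scaled
# trapezoid AUC equals that balanced accuracy.
.aucSafe <- function(curve, range = c(0.002, 0.10)) {
  ok <- is.finite(curve$baCertain)
  if (sum(ok) == 1) return(curve$baCertain[ok])
  certaintyAUC(curve, range)
}

#' Run the full experiment
#'
#' Generates the development and out-of-distribution cohorts, makes K
#' patient-level splits, trains one network per (split, method) pair,
#' anchors the 50-interval grid on each network's validation sigmoids
#' and evaluates: balanced accuracy, validation distance-to-threshold
#' by reader consistency, the certainty curve and its AUC on the
#' in-distribution test subset, observed-versus-target regression
#' slopes on the out-of-distribution cohorts, and pairwise
#' Nadeau-Bengio tests on the AUC across realizations.
#'
#' @param config an [experimentConfig()].
#' @param outDir optional directory; when given, tidy CSV tables and a
#'   JSON manifest are written there.
#' @param verbose print per-stage progress.
#' @return a list of class `SpectExperiment` with elements `config`,
#'   `cohortSummary`, `metrics` (one row per method x realization),
#'   `curves`, `grids`, `oodObserved`, `nbTests` and `manifest`.
#' @export
runExperiment <- function(config = experimentConfig(), outDir = NULL,
                          verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  spec <- archSpec(config$imageSize, config$widthMult)

  say("generating development cohort (%d scans) ...", config$nScans)
  cohort <- generateCohort(cohortConfig(
    nScans = config$nScans, imageSize = config$imageSize,
    seed = deriveSeed(config$seed, 1)))
  oods <- list()
  for (pr in config$oodProfiles) {
    say("generating %s cohort (%d scans) ...", pr, config$oodScans)
    oods[[pr]] <- generateOodCohort(cohortConfig(
      nScans = config$oodScans, imageSize = config$imageSize,
      oodProfile = pr,
      seed = deriveSeed(config$seed, 2 + match(pr, .oodProfiles))))
  }
  scans <- scanInfo(cohort)
  votes <- readerVotes(cohort)
  majority <- majorityVote(votes)
  splits <- makeSplits(scans$scan_id, K = config$K,
                       seed = deriveSeed(config$seed, 4))

  metrics <- list()
  curves <- list()
  grids <- list()
  oodObserved <- list()
  for (k in seq_len(config$K)) {
    sk <- splits[splits$realization == k, ]
    initSeed <- deriveSeed(config$seed, 50 + k)
    for (method in config$methods) {
      tag <- sprintf("%s.r%d", method, k)
      tcfg <- trainingConfig(method, epochs = config$epochs,
                             batchSize = config$batchSize,
                             lr = config$lr,
                             seed = deriveSeed(config$seed, 100 + k))
      tA <- proc.time()[3]
      net <- trainNetwork(cohort, sk, tcfg, spec, initSeed = initSeed)
      predVal <- predictSigmoid(net, cohort, splitScans(sk, k, "VAL"))
      predTest <- predictSigmoid(net, cohort, splitScans(sk, k, "TEST"))
      grid <- buildIntervalGrid(predVal$sigmoid, config$gridTargets)
      grids[[tag]] <- grid

      vmatch <- match(predVal$scan_id, scans$scan_id)
      dcv <- distanceByConsistency(predVal$sigmoid,
                                   votes[vmatch, , drop = FALSE])
      getMean <- function(g) {
        i <- which(dcv$group == g)
        if (length(i)) dcv$mean[i] else NA_real_
      }
      truthTest <- majority[match(predTest$scan_id, scans$scan_id)]
      curve <- certaintyCurve(predTest$sigmoid, truthTest, grid)
      curves[[tag]] <- curve

      slopes <- list()
      for (pr in names(oods)) {
        po <- predictSigmoid(net, oods[[pr]])
        obs <- vapply(intervals(grid), function(iv)
          observedProportion(po$sigmoid, iv), numeric(1))
        oodObserved[[paste(tag, pr, sep = ".")]] <-
          data.frame(method = method, realization = k, profile = pr,
                     target = targetProportions(grid), observed = obs)
        slopes[[pr]] <- regressionThroughOrigin(targetProportions(grid),
                                                obs)
      }
      metrics[[tag]] <- data.frame(
        method = method, realization = k,
        finalLoss = net@log$loss[nrow(net@log)],
        baOverall = balancedAccuracy(predTest$prediction, truthTest),
        auc = .aucSafe(curve),
        distConsistent = getMean("consistent"),
        distDiscrepant = getMean("discrepant"),
        separation = getMean("consistent") - getMean("discrepant"),
        slopePPMI = slopes[["PPMI_LIKE"]] %||% NA_real_,
        slopeMPH = slopes[["MPH_LIKE"]] %||% NA_real_,
        stringsAsFactors = FALSE)
      say("%s: loss %.4f, BA %.1f%%, AUC %.1f%% (%.0f s)", tag,
          metrics[[tag]]$finalLoss, metrics[[tag]]$baOverall,
          metrics[[tag]]$auc, proc.time()[3] - tA)
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL

  nbTests <- list()
  if (config$K >= 2 && length(config$methods) >= 2) {
    pairs <- utils::combn(config$methods, 2, simplify = FALSE)
    for (pp in pairs) {
      a <- metrics$auc[metrics$method == pp[1]]
      b <- metrics$auc[metrics$method == pp[2]]
      nbTests[[paste(pp, collapse = "_vs_")]] <- nadeauBengioTest(a, b)
    }
  }

  result <- structure(list(
    config = config,
    cohortSummary = list(
      nScans = nScans(cohort), nImages = nInstances(cohort),
      votePattern = votePatternTable(votes),
      prevalence = mean(trueClasses(cohort))),
    splits = splits, metrics = metrics, curves = curves, grids = grids,
    oodObserved = do.call(rbind, oodObserved),
    nbTests = nbTests,
    manifest = list(seed = config$seed,
                    package = as.character(utils::packageVersion("SpectCertainty")),
                    elapsedSec = unname(proc.time()[3] - t0),
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "SpectExperiment")
  if (!is.null(outDir)) writeExperiment(result, outDir)
  result
}

#' Write experiment tables
#'
#' @param result a `SpectExperiment`.
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeExperiment <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$metrics, file.path(outDir, "metrics.csv"),
            row.names = FALSE)
  write.csv(result$oodObserved, file.path(outDir, "ood_observed.csv"),
            row.names = FALSE)
  gridTab <- do.call(rbind, lapply(names(result$grids), function(tag) {
    df <- as.data.frame(result$grids[[tag]])
    df$model <- tag
    df
  }))
  write.csv(gridTab, file.path(outDir, "intervals.csv"),
            row.names = FALSE)
  summary <- list(
    cohort = result$cohortSummary,
    meanByMethod = lapply(split(result$metrics, result$metrics$method),
                          function(df) lapply(df[, -(1:2)], mean)),
    nbTests = lapply(result$nbTests, function(h)
      list(t = unname(h$statistic), df = unname(h$parameter),
           p = h$p.value)),
    manifest = result$manifest)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' @export
print.SpectExperiment <- function(x, ...) {
  cat("SpectExperiment:", x$cohortSummary$nScans, "scans,",
      x$config$K, "realizations,",
      paste(x$config$methods, collapse = "/"), "\n")
  agg <- aggregate(cbind(baOverall, auc, separation) ~ method,
                   data = x$metrics, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}
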