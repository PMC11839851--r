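#' SlabCohort: a cohort of synthetic striatal SPECT slab images
#'
#' Container for a synthetic cohort.  Pixel data for all augmentation
#' instances are held in one `(H, W, M)` array; two data frames describe
#' the instances (one row per image) and the scans (one row per
#' subject), and a binary matrix holds the reader votes (one column per
#' reader; out-of-distribution cohorts carry a single reference-label
#' column).
#'
#' @slot images numeric array `(H, W, M)`, non-negative intensities.
#' @slot instances data.frame with columns `instance_id`, `scan_id`,
#'   `variant` (`"ASC"`/`"NOASC"`), `smoothing_fwhm_mm`.
#' @slot scans data.frame with columns `scan_id`, `severity`,
#'   `true_class`.
#' @slot votes integer matrix, `nScans x R`, entries 0 (normal) or
#'   1 (reduced), rownames = `scan_id`.
#' @slot profile `"IN_DIST"`, `"PPMI_LIKE"` or `"MPH_LIKE"`.
#' @slot config the [cohortConfig()] list the cohort was generated from.
#' @export
setClass("SlabCohort",
  representation(
    images = "array",
    instances = "data.frame",
    scans = "data.frame",
    votes = "matrix",
    profile = "character",
    config = "list"
  )
)

setValidity("SlabCohort", function(object) {
  msg <- character()
  d <- dim(object@images)
  if (length(d) != 3) msg <- c(msg, "images must be a (H, W, M) array")
  if (length(d) == 3 && d[3] != nrow(object@instances))
    msg <- c(msg, "third image dimension must equal nrow(instances)")
  need <- c("instance_id", "scan_id", "variant", "smoothing_fwhm_mm")
  if (!all(need %in% names(object@instances)))
    msg <- c(msg, "instances must have instance_id, scan_id, variant, smoothing_fwhm_mm")
  need <- c("scan_id", "severity", "true_class")
  if (!all(need %in% names(object@scans)))
    msg <- c(msg, "scans must have scan_id, severity, true_class")
  if (nrow(object@votes) != nrow(object@scans))
    msg <- c(msg, "votes must have one row per scan")
  if (length(object@votes) && !all(object@votes %in% c(0L, 1L)))
    msg <- c(msg, "votes must be 0/1")
  if (any(object@scans$severity < 0 | object@scans$severity > 1))
    msg <- c(msg, "severity must lie in [0, 1]")
  perScan <- table(object@instances$scan_id)
  expected <- if (identical(object@profile, "IN_DIST")) 12L else 1L
  if (length(perScan) && !all(perScan == expected))
    msg <- c(msg, sprintf("every scan must have exactly %d instances", expected))
  if (length(object@images) && (anyNA(object@images) || min(object@images) < 0))
    msg <- c(msg, "image intensities must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn SlabCohort number of scans (subjects).
#' @param x,object a `SlabCohort`.
#' @export
setMethod("nScans", "SlabCohort", function(x) nrow(x@scans))

#' @describeIn SlabCohort number of image instances.
#' @export
setMethod("nInstances", "SlabCohort", function(x) nrow(x@instances))

#' @describeIn SlabCohort per-scan metadata data.frame.
#' @export
setMethod("scanInfo", "SlabCohort", function(x) x@scans)

#' @describeIn SlabCohort per-instance metadata data.frame.
#' @export
setMethod("instanceInfo", "SlabCohort", function(x) x@instances)

#' @describeIn SlabCohort reader vote matrix (scans x readers).
#' @export
setMethod("readerVotes", "SlabCohort", function(x) x@votes)

#' @describeIn SlabCohort latent severity per scan.
#' @export
setMethod("severities", "SlabCohort", function(x) x@scans$severity)

#' @describeIn SlabCohort generator ground-truth class per scan (0/1).
#' @export
setMethod("trueClasses", "SlabCohort", function(x) x@scans$true_class)

#' @describeIn SlabCohort extract the `i`-th instance image as a matrix.
#' @param i instance index.
#' @export
setMethod("slabImage", "SlabCohort", function(x, i) x@images[, , i])

#' @describeIn SlabCohort subset by scan index (keeps all instances of
#'   the selected scans).
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "SlabCohort", function(x, i, j, ..., drop = FALSE) {
  scans <- x@scans[i, , drop = FALSE]
  keep <- x@instances$scan_id %in% scans$scan_id
  initialize(x,
    images = x@images[, , keep, drop = FALSE],
    instances = x@instances[keep, , drop = FALSE],
    scans = scans,
    votes = x@votes[i, , drop = FALSE]
  )
})

setMethod("show", "SlabCohort", function(object) {
  d <- dim(object@images)
  cat(sprintf("SlabCohort (%s): %d scans, %d instances of %dx%d pixels\n",
              object@profile, nScans(object), nInstances(object), d[1], d[2]))
  cat(sprintf("  readers: %d | reduced (truth): %.1f%% | unanimity: %.1f%%\n",
              ncol(object@votes),
              100 * mean(object@scans$true_class),
              100 * mean(apply(object@votes, 1, function(v) length(unique(v)) == 1))))
})

#' InconclusiveInterval: an abstention band on the sigmoid output
#'
#' The interval `[lower, upper]` around the 0.5 decision threshold that
#' flags cases as inconclusive.  Built from validation sigmoid outputs
#' so that a target proportion of validation cases falls inside, with
#' equally many below and above the threshold.  A degenerate interval
#' (`nBelow == 0`) contains no case.
#'
#' @slot lower,upper numeric bounds (`NA` when degenerate).
#' @slot targetProportion the target proportion it was built for.
#' @slot nBelow,nAbove number of selected validation cases on each side.
#' @slot clipped TRUE when a side had fewer cases than requested.
#' @export
setClass("InconclusiveInterval",
  representation(
    lower = "numeric", upper = "numeric",
    targetProportion = "numeric",
    nBelow = "integer", nAbove = "integer",
    clipped = "logical"
  )
)

setValidity("InconclusiveInterval", function(object) {
  if (object@nBelow > 0 &&
      (!is.finite(object@lower) || !is.finite(object@upper) ||
       object@lower > object@upper))
    return("non-degenerate interval needs finite lower <= upper")
  TRUE
})

#' @describeIn InconclusiveInterval width of the interval as percent of
#'   the sigmoid range (0, 1); 0 for a degenerate interval.
#' @param x,object an `InconclusiveInterval`.
#' @export
setMethod("coverage", "InconclusiveInterval", function(x) {
  if (x@nBelow == 0L && x@nAbove == 0L) return(0)
  100 * (x@upper - x@lower)
})

setMethod("show", "InconclusiveInterval", function(object) {
  if (object@nBelow == 0L && object@nAbove == 0L) {
    cat(sprintf("InconclusiveInterval (target %.1f%%): degenerate (empty)\n",
                100 * object@targetProportion))
  } else {
    cat(sprintf(
      "InconclusiveInterval (target %.1f%%): [%.4f, %.4f], n = %d + %d%s\n",
      100 * object@targetProportion, object@lower, object@upper,
      object@nBelow, object@nAbove,
      if (object@clipped) " (clipped)" else ""))
  }
})

#' IntervalGrid: inconclusive intervals over a grid of target proportions
#'
#' @slot targets target proportions (fractions), default the 50-point
#'   grid 0.2\%, 0.4\%, ..., 10.0\%.
#' @slot intervals list of [InconclusiveInterval-class] objects.
#' @export
setClass("IntervalGrid",
  representation(targets = "numeric", intervals = "list")
)

setValidity("IntervalGrid", function(object) {
  if (length(object@targets) != length(object@intervals))
    return("one interval per target required")
  if (is.unsorted(object@targets, strictly = TRUE))
    return("targets must be strictly increasing")
  TRUE
})

#' @describeIn IntervalGrid list of intervals.
#' @param x,object an `IntervalGrid`.
#' @export
setMethod("intervals", "IntervalGrid", function(x) x@intervals)

#' @describeIn IntervalGrid the target proportions.
#' @export
setMethod("targetProportions", "IntervalGrid", function(x) x@targets)

setMethod("show", "IntervalGrid", function(object) {
  cat(sprintf("IntervalGrid: %d targets from %.1f%% to %.1f%%\n",
              length(object@targets), 100 * min(object@targets),
              100 * max(object@targets)))
})

#' @describeIn IntervalGrid coerce to a data.frame (one row per target).
#' @param row.names,optional,... passed conventions, ignored.
#' @export
setMethod("as.data.frame", "IntervalGrid",
  function(x, row.names = NULL, optional = FALSE, ...) {
    do.call(rbind, lapply(x@intervals, function(iv) {
      data.frame(target_proportion = iv@targetProportion,
                 lower = iv@lower, upper = iv@upper,
                 n_below = iv@nBelow, n_above = iv@nAbove,
                 clipped = iv@clipped)
    }))
  })

#' DatNet: a compact single-channel residual network
#'
#' Handle to a ResNet-18-style classifier (single input channel, single
#' sigmoid output).  Weights, batch-norm running statistics and
#' optimizer state live in an environment so training can update them
#' in place; everything else is immutable metadata.
#'
#' @slot spec the [archSpec()] list (input size, stage widths, ...).
#' @slot env environment with `params`, `state` and (after training)
#'   `opt`.
#' @slot method training method tag ("MVT", "RVT", "AVT" or "untrained").
#' @slot log per-epoch mean training loss (data.frame).
#' @slot seeds named list of the seeds used (init / shuffle / labels).
#' @export
setClass("DatNet",
  representation(
    spec = "list", env = "environment", method = "character",
    log = "data.frame", seeds = "list"
  )
)

setMethod("show", "DatNet", function(object) {
  acct <- parameterAccount(object@spec)
  cat(sprintf(
    "DatNet (%s): input %dx%d, widths %s, %s parameters\n",
    object@method, object@spec$inputSize, object@spec$inputSize,
    paste(object@spec$widths, collapse = "/"),
    format(acct$total, big.mark = ",")))
  if (nrow(object@log))
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                nrow(object@log), object@log$loss[nrow(object@log)]))
})
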