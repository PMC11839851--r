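# Inconclusive intervals on the sigmoid output --------------------------
#
# The interval is anchored on the validation set: for a target
# proportion p of n validation cases, the k = round(p*n/2) cases
# closest to the 0.5 decision threshold on each side are selected
# (sigmoids exactly at 0.5 count as "below", consistent with the <= 0.5
# decision rule).  Each bound is placed at the midpoint between the
# outermost selected case and its nearest excluded neighbour on that
# side, or at the side's extreme value when the whole side is selected,
# so re-applying the interval to the validation sigmoids recovers
# exactly the selected cases (up to exact value ties).  Distance ties
# within a side are broken by case order, deterministically.

#' Construct an inconclusive interval directly from bounds
#'
#' Mostly useful for arithmetic on published bounds; intervals anchored
#' in data come from [determineInterval()].
#'
#' @param lower,upper interval bounds on the sigmoid scale.
#' @param targetProportion the target proportion the interval is meant
#'   to represent.
#' @return an [InconclusiveInterval-class].
#' @export
inconclusiveInterval <- function(lower, upper, targetProportion = NA_real_) {
  new("InconclusiveInterval", lower = lower, upper = upper,
      targetProportion = targetProportion, nBelow = 1L, nAbove = 1L,
      clipped = FALSE)
}

#' Determine the inconclusive interval from validation sigmoids
#'
#' @param sigmoids validation sigmoid outputs.
#' @param targetProportion target proportion of inconclusive cases in
#'   `(0, 1]`.
#' @return an [InconclusiveInterval-class].  With `k = 0` the interval
#'   is degenerate (no case inconclusive).  If a side holds fewer than
#'   `k` cases the whole side is taken and the interval is flagged
#'   `clipped` with a warning.
#' @examples
#' s <- c(0.1, 0.2, 0.3, 0.4, 0.45, 0.55, 0.6, 0.7, 0.8, 0.9)
#' determineInterval(s, 0.4)  # bounds (0.35, 0.65)
#' @export
determineInterval <- function(sigmoids, targetProportion) {
  if (!length(sigmoids)) stop("empty sigmoid vector")
  if (anyNA(sigmoids)) stop("sigmoids must not contain NA")
  if (targetProportion <= 0 || targetProportion > 1)
    stop("targetProportion must lie in (0, 1]")
  n <- length(sigmoids)
  k <- as.integer(roundHalfUp(targetProportion * n / 2))
  ids <- seq_len(n)
  below <- which(sigmoids <= 0.5)
  above <- which(sigmoids > 0.5)

  if (k == 0L)
    return(new("InconclusiveInterval", lower = NA_real_, upper = NA_real_,
               targetProportion = targetProportion, nBelow = 0L,
               nAbove = 0L, clipped = FALSE))

  clipped <- k > length(below) || k > length(above)
  if (clipped)
    warning(sprintf(
      "target needs %d cases per side; only %d below / %d above available",
      k, length(below), length(above)))

  pickSide <- function(side, k) {
    # indices of the k cases closest to 0.5, ties by case order
    o <- side[order(abs(sigmoids[side] - 0.5), ids[side])]
    utils::head(o, k)
  }
  kB <- min(k, length(below))
  kA <- min(k, length(above))
  inB <- pickSide(below, kB)
  inA <- pickSide(above, kA)

  lower <- if (kB == 0L) 0.5 else {
    sel <- sigmoids[inB]
    rest <- sigmoids[setdiff(below, inB)]
    if (length(rest)) (min(sel) + max(rest)) / 2 else min(sel)
  }
  upper <- if (kA == 0L) 0.5 else {
    sel <- sigmoids[inA]
    rest <- sigmoids[setdiff(above, inA)]
    if (length(rest)) (max(sel) + min(rest)) / 2 else max(sel)
  }
  new("InconclusiveInterval", lower = lower, upper = upper,
      targetProportion = targetProportion, nBelow = as.integer(kB),
      nAbove = as.integer(kA), clipped = clipped)
}

#' Build the 50-interval grid
#'
#' One interval per target proportion 0.2\%, 0.4\%, ..., 10.0\% (by
#' default), all anchored on the same validation sigmoids.  Intervals
#' are nested: a higher target contains every lower-target interval.
#'
#' @param sigmoids validation sigmoid outputs.
#' @param targets target proportions (strictly increasing fractions).
#' @return an [IntervalGrid-class].
#' @export
buildIntervalGrid <- function(sigmoids, targets = (1:50) / 500) {
  new("IntervalGrid", targets = targets,
      intervals = lapply(targets, function(p)
        determineInterval(sigmoids, p)))
}

#' Classify cases as certain or inconclusive
#'
#' @param sigmoids sigmoid outputs of the cases to classify.
#' @param interval an [InconclusiveInterval-class].
#' @return character vector of flags, `"CERTAIN"` or `"INCONCLUSIVE"`;
#'   a case is inconclusive iff `lower <= s <= upper` (inclusive
#'   bounds).  A degenerate interval flags everything certain.
#' @export
classifyCertainty <- function(sigmoids, interval) {
  if (interval@nBelow == 0L && interval@nAbove == 0L)
    return(rep("CERTAIN", length(sigmoids)))
  ifelse(sigmoids >= interval@lower & sigmoids <= interval@upper,
         "INCONCLUSIVE", "CERTAIN")
}

#' Proportion of cases inside an interval
#'
#' @inheritParams classifyCertainty
#' @return fraction of `sigmoids` flagged inconclusive.
#' @export
observedProportion <- function(sigmoids, interval) {
  mean(classifyCertainty(sigmoids, interval) == "INCONCLUSIVE")
}
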