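# Performance metrics and statistics ------------------------------------

#' Confusion counts
#'
#' @param predictions predicted classes (0/1, positive = "reduced").
#' @param truth reference classes (0/1).
#' @return list with `tp`, `fn`, `tn`, `fp`.
#' @export
confusionCounts <- function(predictions, truth) {
  if (length(predictions) != length(truth)) stop("length mismatch")
  list(tp = sum(predictions == 1 & truth == 1),
       fn = sum(predictions == 0 & truth == 1),
       tn = sum(predictions == 0 & truth == 0),
       fp = sum(predictions == 1 & truth == 0))
}

#' Balanced accuracy
#'
#' `100 * (sensitivity + specificity) / 2`, with sensitivity
#' `tp / (tp + fn)` and specificity `tn / (tn + fp)` for the positive
#' class "reduced".  Undefined (`NA`) when a class is absent; callers
#' must propagate the gap rather than impute it.
#'
#' @param predictions predicted classes, or a [confusionCounts()] list
#'   if `truth` is missing.
#' @param truth reference classes.
#' @return balanced accuracy in percent, or `NA`.
#' @examples
#' balancedAccuracy(c(1, 1, 0), c(1, 0, 0))  # 75
#' @export
balancedAccuracy <- function(predictions, truth) {
  cc <- if (missing(truth)) predictions else
    confusionCounts(predictions, truth)
  if (cc$tp + cc$fn == 0 || cc$tn + cc$fp == 0) return(NA_real_)
  100 * (cc$tp / (cc$tp + cc$fn) + cc$tn / (cc$tn + cc$fp)) / 2
}

#' Certainty curve
#'
#' For every interval of the grid, applies it to the test sigmoids and
#' records the observed (not target) proportion of inconclusive cases
#' together with the balanced accuracy computed separately in the
#' certain and the inconclusive cases.  Undefined balanced accuracies
#' (a stratum missing a class) are kept as `NA` gaps.  Duplicate
#' observed proportions are collapsed keeping the last (largest-target)
#' point.
#'
#' @param sigmoids test sigmoid outputs.
#' @param truth reference classes (0/1) of the test cases.
#' @param grid an [IntervalGrid-class] anchored on validation data.
#' @return data.frame with `target`, `observed`, `baCertain`,
#'   `baInconclusive`.
#' @export
certaintyCurve <- function(sigmoids, truth, grid) {
  if (length(sigmoids) != length(truth)) stop("length mismatch")
  pred <- as.integer(sigmoids > 0.5)
  pts <- lapply(intervals(grid), function(iv) {
    flag <- classifyCertainty(sigmoids, iv)
    cert <- flag == "CERTAIN"
    data.frame(
      target = iv@targetProportion,
      observed = mean(!cert),
      baCertain = if (any(cert))
        balancedAccuracy(pred[cert], truth[cert]) else NA_real_,
      baInconclusive = if (any(!cert))
        balancedAccuracy(pred[!cert], truth[!cert]) else NA_real_)
  })
  out <- do.call(rbind, pts)
  # collapse duplicate abscissae, keep the last
  out <- out[!duplicated(out$observed, fromLast = TRUE), , drop = FALSE]
  out[order(out$observed), , drop = FALSE]
}

#' Area under the certainty curve
#'
#' Trapezoid integral of the certain-case balanced accuracy over the
#' observed proportion of inconclusive cases, evaluated on
#' `range` (default 0.2\% to 10\%) and scaled to the maximum possible
#' area, so 100 means perfect balanced accuracy in the certain cases
#' throughout.  The curve is linearly interpolated to the range
#' endpoints (constant extrapolation if no observed proportion reaches
#' an endpoint).
#'
#' @param curve a [certaintyCurve()] data.frame.
#' @param range integration range on the observed-proportion axis.
#' @return AUC in percent.
#' @examples
#' curve <- data.frame(observed = c(0.002, 0.10), baCertain = c(90, 100))
#' certaintyAUC(curve)  # 95
#' @export
certaintyAUC <- function(curve, range = c(0.002, 0.10)) {
  ok <- is.finite(curve$baCertain)
  x <- curve$observed[ok]
  y <- curve$baCertain[ok]
  if (length(x) < 2)
    stop("need at least two curve points with defined balanced accuracy")
  o <- order(x)
  x <- x[o]
  y <- y[o]
  xs <- sort(unique(c(range, x[x > range[1] & x < range[2]])))
  ys <- approx(x, y, xout = xs, rule = 2, ties = "ordered")$y
  area <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  100 * area / (100 * (range[2] - range[1]))
}

#' Regression through the origin
#'
#' Least-squares slope of `observed ~ target` without a constant,
#' `sum(x y) / sum(x^2)`.  A slope above 1 means the method labels more
#' test cases inconclusive than intended.
#'
#' @param targets intended target proportions.
#' @param observed observed proportions.
#' @return the slope.
#' @export
regressionThroughOrigin <- function(targets, observed) {
  if (!length(targets) || length(targets) != length(observed))
    stop("targets and observed must be non-empty and equally long")
  if (all(targets == 0)) stop("all-zero targets")
  sum(targets * observed) / sum(targets^2)
}

#' Sigmoid distance by reader consistency
#'
#' Compares the distance of the sigmoid output from the 0.5 decision
#' threshold between cases whose readers were unanimous ("consistent")
#' and cases with between-reader discrepancy ("discrepant"), reporting
#' group means with normal-approximation 95\% confidence intervals.
#'
#' @param sigmoids per-case sigmoid outputs.
#' @param votes per-case vote matrix (rows aligned with `sigmoids`).
#' @return data.frame with one row per non-empty group: `group`, `n`,
#'   `mean`, `ciLow`, `ciHigh`.
#' @export
distanceByConsistency <- function(sigmoids, votes) {
  if (nrow(votes) != length(sigmoids)) stop("votes/sigmoids mismatch")
  dist <- abs(sigmoids - 0.5)
  consistent <- rowSums(votes) %in% c(0, ncol(votes))
  groups <- list(consistent = dist[consistent],
                 discrepant = dist[!consistent])
  out <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (!length(d)) return(NULL)
    se <- if (length(d) > 1) sd(d) / sqrt(length(d)) else 0
    data.frame(group = g, n = length(d), mean = mean(d),
               ciLow = mean(d) - 1.96 * se, ciHigh = mean(d) + 1.96 * se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Corrected resampled paired t-test
#'
#' Paired t-test across `K` random-split realizations with the
#' Nadeau-Bengio variance correction
#' `t = mean(d) / sqrt((1/K + rho) * var(d))`, which accounts for the
#' overlap of training sets across splits; `rho` is the test-to-train
#' size ratio (1/3 for a 60/20/20 design).  Degrees of freedom `K - 1`;
#' as `rho -> 0` the statistic reduces to the classical paired t.
#'
#' @param x,y per-realization metric values of the two methods;
#'   alternatively pass the paired differences as `x` and omit `y`.
#' @param rho test-to-train size ratio.
#' @return an object of class `htest`.
#' @examples
#' nadeauBengioTest(1:10, rep(0, 10))$statistic  # about 2.759
#' @export
nadeauBengioTest <- function(x, y = NULL, rho = 1 / 3) {
  d <- if (is.null(y)) x else x - y
  K <- length(d)
  if (K < 2) stop("need at least 2 paired realizations")
  if (rho <= 0) stop("rho must be positive")
  v <- var(d)
  m <- mean(d)
  if (v == 0) {
    if (m == 0) {
      t <- 0
      p <- 1
    } else {
      warning("zero variance with non-zero mean difference")
      t <- sign(m) * Inf
      p <- 0
    }
  } else {
    t <- m / sqrt((1 / K + rho) * v)
    p <- 2 * pt(-abs(t), df = K - 1)
  }
  structure(list(
    statistic = c(t = t), parameter = c(df = K - 1),
    p.value = p, estimate = c(`mean difference` = m),
    method = "Corrected resampled paired t-test (Nadeau-Bengio)",
    data.name = sprintf("%d paired realizations, rho = %.3f", K, rho),
    rho = rho), class = "htest")
}
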