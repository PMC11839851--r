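# Simulated reader panel -------------------------------------------------
#
# Each reader r votes "reduced" (1) iff severity + eps_r exceeds the
# reader's personal decision threshold, eps_r ~ N(0, noiseSd_r).
# Discrepant votes therefore arise only near the thresholds, i.e. for
# borderline scans: class overlap, not annotation noise, drives the
# disagreement.  The default model is calibrated (by numerical
# integration against the default severity mixture) so that the four
# vote-pattern frequencies match the published development-cohort
# table: 49.1% unanimous normal, 2.8% reduced-by-1, 2.0% reduced-by-2,
# 46.1% unanimous reduced (95.2% unanimity).

#' Reader panel model
#'
#' @param thresholds per-reader decision thresholds on the latent
#'   severity scale.
#' @param noiseSd per-reader perceptual noise standard deviations
#'   (recycled to the number of readers).
#' @return a list of class `ReaderModel`.
#' @export
readerModel <- function(thresholds, noiseSd) {
  if (length(thresholds) < 1) stop("at least one reader is required")
  noiseSd <- rep_len(noiseSd, length(thresholds))
  if (any(noiseSd < 0)) stop("noiseSd must be non-negative")
  structure(list(thresholds = thresholds, noiseSd = noiseSd),
            class = "ReaderModel")
}

#' @rdname readerModel
#' @export
defaultReaderModel <- function() {
  readerModel(thresholds = c(0.46192, 0.51119, 0.54596),
              noiseSd = 0.012)
}

#' Simulate the reader panel for one scan
#'
#' @param severity latent severity of the scan.
#' @param model a [readerModel()].
#' @param seed seed for the perceptual noise draws.
#' @return integer vector of votes (0 = normal, 1 = reduced), one per
#'   reader.  With zero noise and identical thresholds the panel is
#'   always unanimous.
#' @export
simulateReaders <- function(severity, model = defaultReaderModel(),
                            seed = 1) {
  stopIfNot01(severity, "severity")
  R <- length(model$thresholds)
  eps <- withSeed(seed, rnorm(R, sd = model$noiseSd))
  as.integer(severity + eps > model$thresholds)
}

#' Simulate the reader panel for many scans at once
#'
#' @param severities vector of latent severities.
#' @param model a [readerModel()].
#' @param seed seed for the perceptual noise draws.
#' @return integer matrix, `length(severities) x R`.
#' @export
simulateReaderPanel <- function(severities, model = defaultReaderModel(),
                                seed = 1) {
  stopIfNot01(severities, "severities")
  n <- length(severities)
  R <- length(model$thresholds)
  eps <- withSeed(seed, matrix(rnorm(n * R), n, R))
  eps <- sweep(eps, 2, model$noiseSd, `*`)
  perceived <- severities + eps
  votes <- matrix(0L, n, R)
  votes[sweep(perceived, 2, model$thresholds, `>`)] <- 1L
  colnames(votes) <- paste0("reader_", seq_len(R))
  votes
}

#' Tabulate vote-pattern frequencies
#'
#' @param votes a 0/1 vote matrix (scans x readers).
#' @return named vector of the observed proportions of scans with 0, 1,
#'   ..., R "reduced" votes.
#' @export
votePatternTable <- function(votes) {
  R <- ncol(votes)
  counts <- tabulate(rowSums(votes) + 1L, nbins = R + 1L)
  stats::setNames(counts / nrow(votes), paste0("reduced_by_", 0:R))
}

#' Exact vote-pattern probabilities under the generator model
#'
#' Integrates the reader model over the severity mixture to obtain the
#' exact probabilities of the `R + 1` vote patterns (number of "reduced"
#' votes).  Used to calibrate the defaults and as an analytic oracle in
#' tests.
#'
#' @param severityModel a [defaultSeverityModel()]-style list.
#' @param model a [readerModel()].
#' @return named numeric vector of length `R + 1`.
#' @export
votePatternProbs <- function(severityModel = defaultSeverityModel(),
                             model = defaultReaderModel()) {
  R <- length(model$thresholds)
  pReduced <- function(s) {
    vapply(seq_len(R), function(r) {
      if (model$noiseSd[r] == 0) as.numeric(s > model$thresholds[r])
      else pnorm((s - model$thresholds[r]) / model$noiseSd[r])
    }, numeric(length(s)))
  }
  patternGivenS <- function(s, k) {
    p <- matrix(pReduced(s), ncol = R)
    # P(exactly k of R), Poisson-binomial via elementary symmetric recursion
    out <- numeric(length(s))
    for (i in seq_along(s)) {
      poly <- 1
      for (r in seq_len(R))
        poly <- c(poly * (1 - p[i, r]), 0) + c(0, poly * p[i, r])
      out[i] <- poly[k + 1]
    }
    out
  }
  dens <- severityDensity(severityModel)
  vapply(0:R, function(k) {
    stats::integrate(function(s) dens(s) * patternGivenS(s, k), 0, 1,
                     subdivisions = 400L, rel.tol = 1e-7)$value
  }, numeric(1)) -> probs
  stats::setNames(probs, paste0("reduced_by_", 0:R))
}
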