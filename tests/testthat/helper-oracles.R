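# Independent oracles used across test files.

# Equal-sided interval selection by exhaustive pairwise counting: a case
# on a side is selected iff fewer than k cases on that side are strictly
# closer to the threshold (ties broken by case index).  O(n^2), written
# without sorting so it is independent of the implementation.
oracleSelect <- function(sigmoids, k) {
  n <- length(sigmoids)
  dist <- abs(sigmoids - 0.5)
  side <- ifelse(sigmoids <= 0.5, "below", "above")
  sel <- logical(n)
  for (i in seq_len(n)) {
    same <- which(side == side[i])
    rank <- sum(dist[same] < dist[i] | (dist[same] == dist[i] & same < i))
    sel[i] <- rank < k
  }
  sel
}

# Brute-force trapezoid on explicit points (for AUC cross-checks).
oracleTrapezoid <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# A tiny, quick in-distribution cohort for pipeline tests.
tinyCohort <- function(nScans = 12, imageSize = 32, seed = 11, ...) {
  generateCohort(cohortConfig(nScans = nScans, imageSize = imageSize,
                              pixelSizeMm = 6, seed = seed, ...))
}
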