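# Reference-label aggregation -------------------------------------------
#
# Three schemes turn a panel of R binary reader votes into the per-
# presentation reference label used during training: the majority vote
# (MVT), a vote drawn uniformly at random at every presentation (RVT),
# and the proportion of "reduced" votes (AVT).  For unanimous panels
# all three coincide; for odd R the majority vote equals the average
# vote rounded to the nearest integer.

.checkVotes <- function(votes) {
  if (is.matrix(votes)) {
    if (ncol(votes) < 1 || nrow(votes) < 1) stop("empty vote matrix")
    if (!all(votes %in% c(0, 1))) stop("votes must be 0 or 1")
  } else {
    if (length(votes) < 1) stop("empty vote tuple")
    if (!all(votes %in% c(0, 1))) stop("votes must be 0 or 1")
    votes <- matrix(as.integer(votes), nrow = 1)
  }
  votes
}

#' Majority-vote reference label
#'
#' @param votes integer vector of one scan's votes, or a scans x readers
#'   matrix (0 = normal, 1 = reduced).
#' @param tieBreak label returned on an even-panel tie; defaults to 1
#'   ("reduced"), the clinically conservative call.  Ties cannot occur
#'   for an odd number of readers.
#' @return integer label(s) in `{0, 1}`.
#' @examples
#' majorityVote(c(1, 1, 0))  # 1
#' @export
majorityVote <- function(votes, tieBreak = 1L) {
  v <- .checkVotes(votes)
  s <- rowSums(v)
  R <- ncol(v)
  out <- ifelse(s * 2 == R, as.integer(tieBreak), as.integer(s > R / 2))
  if (is.matrix(votes)) out else out[1]
}

#' Average-vote reference label
#'
#' The proportion of "reduced" votes, `k / R`; fractional for
#' discrepant panels.
#'
#' @inheritParams majorityVote
#' @return numeric label(s) in `[0, 1]`.
#' @examples
#' averageVote(c(0, 1, 0))  # 1/3
#' @export
averageVote <- function(votes) {
  v <- .checkVotes(votes)
  out <- rowMeans(v)
  if (is.matrix(votes)) out else out[1]
}

#' Random-vote reference label
#'
#' Selects one of the `R` votes uniformly at random, consuming the
#' *current* R random number stream: the caller seeds the stream once
#' per training run, so repeated calls across epochs yield fresh draws
#' (the expectation over draws equals [averageVote()]).
#'
#' @inheritParams majorityVote
#' @return integer label(s) in `{0, 1}`.
#' @export
randomVote <- function(votes) {
  v <- .checkVotes(votes)
  if (ncol(v) < 2) stop("random-vote aggregation requires at least 2 readers")
  idx <- sample.int(ncol(v), nrow(v), replace = TRUE)
  out <- v[cbind(seq_len(nrow(v)), idx)]
  if (is.matrix(votes)) as.integer(out) else as.integer(out[1])
}
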