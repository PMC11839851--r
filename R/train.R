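# Patient-level splitting, the three training loops, prediction --------

#' Training configuration
#'
#' The loss is determined by the method: binary cross entropy for MVT
#' and RVT (binary targets), mean squared error on the sigmoid for AVT
#' (fractional targets).
#'
#' @param method "MVT", "RVT" or "AVT".
#' @param epochs number of training epochs.
#' @param batchSize minibatch size.
#' @param lr Adam learning rate.
#' @param seed master seed for the run; the shuffle stream, the
#'   random-vote label stream and (by default) the weight
#'   initialization derive from it.
#' @return a list of class `TrainingConfig`.
#' @export
trainingConfig <- function(method = c("MVT", "RVT", "AVT"), epochs = 20,
                           batchSize = 64, lr = 1e-4, seed = 1) {
  method <- match.arg(method)
  if (lr <= 0) stop("learning rate must be positive")
  if (epochs < 1 || batchSize < 1) stop("epochs and batchSize must be >= 1")
  structure(list(method = method, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), lr = lr,
                 seed = as.integer(seed),
                 loss = if (method == "AVT") "mse" else "bce"),
            class = "TrainingConfig")
}

#' Patient-level train/validation/test splits
#'
#' Randomizes scans (not images) into the three subsets so that all
#' augmentation instances of a scan land in the same subset, and
#' returns `K` independent realizations.  The same splits are reused
#' for every training method.
#'
#' @param scanIds character vector of scan identifiers.
#' @param K number of split realizations.
#' @param proportions train/validation/test proportions (sum to 1);
#'   subset sizes use deterministic rounding
#'   (`round(p1 n)`, `round(p2 n)`, remainder).
#' @param seed integer seed.
#' @return data.frame with columns `realization`, `scan_id`, `subset`
#'   (factor TRAIN/VAL/TEST).
#' @examples
#' sp <- makeSplits(sprintf("s%04d", 1:1740), K = 1)
#' table(sp$subset)  # 1044 / 348 / 348
#' @export
makeSplits <- function(scanIds, K = 10, proportions = c(0.6, 0.2, 0.2),
                       seed = 1) {
  n <- length(scanIds)
  if (n < 3) stop("fewer scans than subsets")
  if (K < 1) stop("K must be at least 1")
  if (abs(sum(proportions) - 1) > 1e-8 || length(proportions) != 3)
    stop("proportions must be three values summing to 1")
  nTr <- roundHalfUp(proportions[1] * n)
  nVa <- roundHalfUp(proportions[2] * n)
  nTe <- n - nTr - nVa
  if (min(nTr, nVa, nTe) < 1) stop("a subset would be empty")
  out <- vector("list", K)
  for (k in seq_len(K)) {
    perm <- withSeed(deriveSeed(seed, k), sample.int(n))
    subset <- factor(rep(c("TRAIN", "VAL", "TEST"), c(nTr, nVa, nTe)),
                     levels = c("TRAIN", "VAL", "TEST"))
    out[[k]] <- data.frame(realization = k, scan_id = scanIds[perm],
                           subset = subset, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Scan ids of one subset of one split realization
#'
#' @param splits a [makeSplits()] data.frame.
#' @param realization realization index.
#' @param subset `"TRAIN"`, `"VAL"` or `"TEST"`.
#' @return character vector of scan ids.
#' @export
splitScans <- function(splits, realization, subset) {
  splits$scan_id[splits$realization == realization &
                   splits$subset == subset]
}

# Per-image intensity normalization: divide by the mean over the
# geometric background region (a distribution-volume-ratio-like
# convention; background ~ 1 after scaling).
normalizeSlabs <- function(images, mask) {
  d <- dim(images)
  mat <- matrix(images, d[1] * d[2])
  bg <- colMeans(mat[as.vector(mask), , drop = FALSE])
  bg[bg <= 0] <- 1
  array(sweep(mat, 2, bg, `/`), d)
}

.cohortMask <- function(cohort) {
  backgroundROI(dim(cohort@images)[1],
                cohort@config$pixelSizeMm %||% 3)
}

# swap the global RNG state; returns the previous state
.swapRNG <- function(state) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  if (is.null(state)) {
    if (!is.null(old)) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  old
}

.lossGrad <- function(z, y, loss) {
  sig <- stats::plogis(z)
  B <- length(z)
  if (loss == "bce") {
    value <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
    dz <- (sig - y) / B
  } else {
    value <- mean((sig - y)^2)
    dz <- 2 * (sig - y) * sig * (1 - sig) / B
  }
  list(value = value, dz = dz)
}

.adamStep <- function(env, grads, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.null(env$opt))
    env$opt <- list(m = rapply(env$params, function(p) p * 0, how = "replace"),
                    v = rapply(env$params, function(p) p * 0, how = "replace"),
                    t = 0L)
  env$opt$t <- env$opt$t + 1L
  t <- env$opt$t
  c1 <- 1 - b1^t
  c2 <- 1 - b2^t
  for (nm in names(grads)) {
    up <- cpp_adam(env$params[[nm]], grads[[nm]], env$opt$m[[nm]],
                   env$opt$v[[nm]], lr, b1, b2, eps, c1, c2)
    env$params[[nm]] <- up$p
    env$opt$m[[nm]] <- up$m
    env$opt$v[[nm]] <- up$v
  }
  invisible(env)
}

#' Train a network under one labelling scheme
#'
#' Trains on the TRAIN images of one split realization.  MVT uses the
#' majority vote as a fixed binary target; AVT uses the vote proportion
#' as a fixed fractional target; RVT redraws one reader's vote per
#' image at every presentation from a single run-level random stream
#' (seeded once, never reset between epochs).
#'
#' @param cohort a [SlabCohort-class] with reader votes.
#' @param split the rows of a [makeSplits()] data.frame belonging to
#'   one realization.
#' @param config a [trainingConfig()].
#' @param spec an [archSpec()]; its input size must match the cohort
#'   images (training does not resize).
#' @param initSeed seed for weight initialization, so different methods
#'   can share identical starting weights; defaults to a seed derived
#'   from `config$seed`.
#' @return a trained [DatNet-class] with a per-epoch loss log.
#' @export
trainNetwork <- function(cohort, split, config, spec = archSpec(64, 0.25),
                         initSeed = deriveSeed(config$seed, 11)) {
  if (length(unique(split$realization)) > 1)
    stop("pass a single split realization")
  votes <- readerVotes(cohort)
  if (config$method %in% c("RVT", "AVT") && ncol(votes) < 2)
    stop(config$method, " requires votes from at least 2 readers")
  if (dim(cohort@images)[1] != spec$inputSize)
    stop("cohort image size and spec$inputSize differ")

  trainScans <- splitScans(split, split$realization[1], "TRAIN")
  inst <- instanceInfo(cohort)
  idx <- which(inst$scan_id %in% trainScans)
  if (!length(idx)) stop("no TRAIN images in this split")
  scanRow <- match(inst$scan_id[idx], scanInfo(cohort)$scan_id)

  X <- normalizeSlabs(cohort@images[, , idx, drop = FALSE],
                      .cohortMask(cohort))
  H <- dim(X)[1]
  nTrain <- length(idx)

  fixedTarget <- switch(config$method,
    MVT = majorityVote(votes)[scanRow],
    AVT = averageVote(votes)[scanRow],
    RVT = NULL)

  net <- buildNetwork(spec, initSeed)
  net@method <- config$method
  env <- net@env

  perms <- withSeed(deriveSeed(config$seed, 12),
                    lapply(seq_len(config$epochs),
                           function(e) sample.int(nTrain)))
  rvtState <- NULL
  if (config$method == "RVT") {
    old <- .swapRNG(NULL)
    set.seed(deriveSeed(config$seed, 13))
    rvtState <- .swapRNG(old)
  }

  log <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_)
  for (epoch in seq_len(config$epochs)) {
    perm <- perms[[epoch]]
    starts <- seq(1, nTrain, by = config$batchSize)
    lossSum <- 0
    for (s in starts) {
      sel <- perm[s:min(s + config$batchSize - 1, nTrain)]
      xb <- array(X[, , sel], c(H, H, 1, length(sel)))
      y <- if (is.null(fixedTarget)) {
        old <- .swapRNG(rvtState)
        lb <- randomVote(votes[scanRow[sel], , drop = FALSE])
        rvtState <- .swapRNG(old)
        lb
      } else fixedTarget[sel]
      fwd <- .nnForward(net, xb, training = TRUE)
      lg <- .lossGrad(fwd$z, y, config$loss)
      grads <- .nnBackward(net, fwd$cache, lg$dz)
      .adamStep(env, grads, config$lr)
      lossSum <- lossSum + lg$value * length(sel)
    }
    log$loss[epoch] <- lossSum / nTrain
  }
  net@log <- log
  net@seeds <- list(init = initSeed,
                    shuffle = deriveSeed(config$seed, 12),
                    labels = if (config$method == "RVT")
                      deriveSeed(config$seed, 13) else NA_integer_)
  net
}

#' Sigmoid predictions for cohort images
#'
#' Runs the network in evaluation mode (batch-norm running statistics,
#' no augmentation) over the selected instances and applies the fixed
#' 0.5 decision rule: prediction 0 ("normal") iff sigmoid <= 0.5.
#'
#' @param net a trained [DatNet-class].
#' @param cohort a [SlabCohort-class].
#' @param scanIds restrict to these scans (default: all).
#' @param batchSize evaluation batch size.
#' @return data.frame with `instance_id`, `scan_id`, `sigmoid`,
#'   `prediction`.
#' @export
predictSigmoid <- function(net, cohort, scanIds = NULL, batchSize = 256) {
  inst <- instanceInfo(cohort)
  idx <- if (is.null(scanIds)) seq_len(nrow(inst)) else
    which(inst$scan_id %in% scanIds)
  if (!length(idx)) stop("no instances selected")
  X <- normalizeSlabs(cohort@images[, , idx, drop = FALSE],
                      .cohortMask(cohort))
  if (dim(X)[1] != net@spec$inputSize) {
    Xr <- array(0, c(net@spec$inputSize, net@spec$inputSize, dim(X)[3]))
    for (i in seq_len(dim(X)[3]))
      Xr[, , i] <- resizeBicubic(X[, , i], net@spec$inputSize)
    X <- Xr
  }
  H <- dim(X)[1]
  n <- dim(X)[3]
  sig <- numeric(n)
  for (s in seq(1, n, by = batchSize)) {
    sel <- s:min(s + batchSize - 1, n)
    xb <- array(X[, , sel], c(H, H, 1, length(sel)))
    sig[sel] <- stats::plogis(.nnForward(net, xb, training = FALSE)$z)
  }
  data.frame(instance_id = inst$instance_id[idx],
             scan_id = inst$scan_id[idx], sigmoid = sig,
             prediction = as.integer(sig > 0.5),
             stringsAsFactors = FALSE)
}
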