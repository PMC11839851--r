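# Compact single-channel ResNet-18 --------------------------------------
#
# Topology: 7x7/2 stem conv (no bias) + BN + ReLU + 3x3/2 max-pool,
# four stages of two basic residual blocks (two 3x3 convs + BN each,
# projection shortcut with 1x1 conv + BN at every stage transition),
# global average pooling and a single-output fully connected layer read
# out through a sigmoid.  `widthMult` scales all stage widths, giving a
# CPU-trainable desk variant of the same topology; `widthMult = 1`
# reproduces the reference architecture exactly.

#' Architecture specification
#'
#' @param inputSize input image side length in pixels (224 for the
#'   fidelity-mode reference network; 64 for the default desk variant).
#' @param widthMult multiplier applied to the reference stage widths
#'   (64, 128, 256, 512).
#' @return a list of class `archSpec` with the derived stage widths.
#' @examples
#' parameterAccount(archSpec(224, 1))$total  # 11,170,753
#' @export
archSpec <- function(inputSize = 224, widthMult = 1) {
  if (inputSize < 32) stop("inputSize must be at least 32 pixels")
  widths <- as.integer(round(c(64, 128, 256, 512) * widthMult))
  if (any(widths < 1)) stop("widthMult too small")
  structure(list(inputSize = as.integer(inputSize),
                 widthMult = widthMult, widths = widths,
                 inputChannels = 1L),
            class = "archSpec")
}

# One descriptor per residual block.
.layerPlan <- function(spec) {
  plan <- list()
  prev <- spec$widths[1]
  for (i in 1:4) {
    w <- spec$widths[i]
    for (j in 1:2) {
      stride <- if (i > 1 && j == 1) 2L else 1L
      inC <- if (j == 1) prev else w
      plan[[sprintf("s%d.b%d", i, j)]] <-
        list(inC = inC, outC = w, stride = stride,
             down = (stride != 1L || inC != w))
    }
    prev <- w
  }
  plan
}

.accountList <- function(spec) {
  w1 <- spec$widths[1]
  rows <- list(
    stem.conv = w1 * spec$inputChannels * 49,
    stem.bn = 2 * w1)
  for (key in names(.layerPlan(spec))) {
    bl <- .layerPlan(spec)[[key]]
    n <- bl$outC * bl$inC * 9 + 2 * bl$outC +    # conv1 + bn1
      bl$outC * bl$outC * 9 + 2 * bl$outC        # conv2 + bn2
    if (bl$down) n <- n + bl$outC * bl$inC + 2 * bl$outC
    rows[[key]] <- n
  }
  rows$fc <- spec$widths[4] + 1
  rows
}

setOldClass("archSpec")

#' @describeIn archSpec exact parameter accounting: one row per named
#'   module (stem conv/BN, each residual block, final linear layer),
#'   the total and trainable counts, and the parameter storage in bytes
#'   and MB (4 bytes per parameter, 1 MB = 1e6 bytes).
#' @param x an `archSpec` (or a [DatNet-class], which delegates to its
#'   spec).
#' @export
setMethod("parameterAccount", "archSpec", function(x) {
  rows <- .accountList(x)
  perLayer <- data.frame(layer = names(rows),
                         params = unlist(rows, use.names = FALSE))
  total <- sum(perLayer$params)
  list(perLayer = perLayer, total = total, trainable = total,
       paramBytes = 4 * total, paramMB = 4 * total / 1e6)
})

#' @describeIn archSpec parameter accounting of a built network.
#' @export
setMethod("parameterAccount", "DatNet", function(x) parameterAccount(x@spec))

#' Input batch storage
#'
#' @param spec an [archSpec()].
#' @param batchSize batch size.
#' @return storage of one input batch in MB (4 bytes per value,
#'   1 MB = 1e6 bytes).
#' @export
inputStorageMB <- function(spec, batchSize = 64) {
  4 * batchSize * spec$inputChannels * spec$inputSize^2 / 1e6
}

.bnKeys <- function(key) paste0(key, c(".gamma", ".beta"))

#' Build (initialize) a network
#'
#' Convolution weights use He initialization (`sd = sqrt(2 / fan_in)`),
#' batch-norm layers start at gamma 1 / beta 0, and the fully connected
#' layer uses the standard uniform fan-in scheme.  Two builds with the
#' same seed are bit-identical.
#'
#' @param spec an [archSpec()].
#' @param seed integer seed for the weight draws.
#' @return an untrained [DatNet-class].
#' @export
buildNetwork <- function(spec = archSpec(64, 0.25), seed = 1) {
  params <- list()
  state <- list()
  withSeed(seed, {
    he <- function(outC, fanIn) {
      matrix(rnorm(outC * fanIn, sd = sqrt(2 / fanIn)), outC, fanIn)
    }
    addBn <- function(key, C) {
      params[[paste0(key, ".gamma")]] <<- rep(1, C)
      params[[paste0(key, ".beta")]] <<- rep(0, C)
      state[[key]] <<- list(rmean = rep(0, C), rvar = rep(1, C))
    }
    w1 <- spec$widths[1]
    params[["stem.conv"]] <- he(w1, spec$inputChannels * 49)
    addBn("stem.bn", w1)
    for (key in names(.layerPlan(spec))) {
      bl <- .layerPlan(spec)[[key]]
      params[[paste0(key, ".conv1")]] <- he(bl$outC, bl$inC * 9)
      addBn(paste0(key, ".bn1"), bl$outC)
      params[[paste0(key, ".conv2")]] <- he(bl$outC, bl$outC * 9)
      addBn(paste0(key, ".bn2"), bl$outC)
      if (bl$down) {
        params[[paste0(key, ".down.conv")]] <- he(bl$outC, bl$inC)
        addBn(paste0(key, ".down.bn"), bl$outC)
      }
    }
    fanIn <- spec$widths[4]
    bound <- 1 / sqrt(fanIn)
    params[["fc.W"]] <- matrix(runif(fanIn, -bound, bound), 1, fanIn)
    params[["fc.b"]] <- runif(1, -bound, bound)
  })
  env <- new.env(parent = emptyenv())
  env$params <- params
  env$state <- state
  new("DatNet", spec = unclass(spec), env = env, method = "untrained",
      log = data.frame(epoch = integer(), loss = numeric()),
      seeds = list(init = seed))
}

.bnMomentum <- 0.1
.bnEps <- 1e-5

# Forward pass.  x is (H, W, 1, N); returns the logit vector and, when
# `keepCache`, everything the backward pass needs.  Updates the
# batch-norm running statistics in net@env when `training`.
.nnForward <- function(net, x, training = FALSE, keepCache = training) {
  env <- net@env
  p <- env$params
  bnF <- function(key, h) {
    st <- env$state[[key]]
    bn <- cpp_bn_fwd(h, p[[paste0(key, ".gamma")]],
                     p[[paste0(key, ".beta")]],
                     st$rmean, st$rvar, .bnMomentum, .bnEps, training)
    if (training) env$state[[key]] <- list(rmean = bn$rmean, rvar = bn$rvar)
    bn
  }
  if (dim(x)[3] != 1L)
    stop(sprintf("network expects a single input channel, got %d", dim(x)[3]))
  cache <- if (keepCache) list(x = x) else NULL

  h <- cpp_conv2d_fwd(x, p[["stem.conv"]], 7L, 7L, 2L, 3L)
  bn <- bnF("stem.bn", h)
  r <- cpp_relu(bn$y)
  mp <- cpp_maxpool_fwd(r, 3L, 2L, 1L)
  if (keepCache)
    cache$stem <- list(conv = h, mean = bn$mean, invstd = bn$invstd,
                       bny = bn$y, poolIdx = mp$idx, poolDim = dim(r))
  h <- mp$y

  for (key in names(.layerPlan(net@spec))) {
    bl <- .layerPlan(net@spec)[[key]]
    xin <- h
    c1 <- cpp_conv2d_fwd(xin, p[[paste0(key, ".conv1")]], 3L, 3L,
                         bl$stride, 1L)
    b1 <- bnF(paste0(key, ".bn1"), c1)
    r1 <- cpp_relu(b1$y)
    c2 <- cpp_conv2d_fwd(r1, p[[paste0(key, ".conv2")]], 3L, 3L, 1L, 1L)
    b2 <- bnF(paste0(key, ".bn2"), c2)
    if (bl$down) {
      cd <- cpp_conv2d_fwd(xin, p[[paste0(key, ".down.conv")]], 1L, 1L,
                           bl$stride, 0L)
      bd <- bnF(paste0(key, ".down.bn"), cd)
      sc <- bd$y
    } else {
      cd <- NULL
      bd <- NULL
      sc <- xin
    }
    h <- cpp_add_relu(b2$y, sc)
    if (keepCache)
      cache[[key]] <- list(xin = xin, c1 = c1, m1 = b1$mean,
                           i1 = b1$invstd, r1 = r1, c2 = c2,
                           m2 = b2$mean, i2 = b2$invstd, cd = cd,
                           md = bd$mean, id = bd$invstd, out = h)
  }

  d <- dim(h)
  hw <- d[1] * d[2]
  pooled <- matrix(colMeans(matrix(h, hw)), d[3], d[4])
  z <- as.vector(p[["fc.W"]] %*% pooled + p[["fc.b"]])
  if (keepCache) {
    cache$gap <- list(hdim = d, pooled = pooled)
  }
  list(z = z, cache = cache)
}

# Backward pass: gradient of the scalar loss wrt every parameter, given
# dL/dz (one value per batch element).  Returns a named gradient list
# parallel to net@env$params.
.nnBackward <- function(net, cache, dz) {
  p <- net@env$params
  grads <- list()
  hdim <- cache$gap$hdim
  hw <- hdim[1] * hdim[2]
  dzr <- matrix(dz, 1)
  grads[["fc.W"]] <- dzr %*% t(cache$gap$pooled)
  grads[["fc.b"]] <- sum(dz)
  dpool <- t(p[["fc.W"]]) %*% dzr                    # C x N
  dout <- array(rep(as.vector(dpool), each = hw) / hw, dim = hdim)

  plan <- .layerPlan(net@spec)
  for (key in rev(names(plan))) {
    bl <- plan[[key]]
    cc <- cache[[key]]
    ds <- cpp_relu_bwd(dout, cc$out)
    bb2 <- cpp_bn_bwd(cc$c2, ds, p[[paste0(key, ".bn2.gamma")]],
                      cc$m2, cc$i2)
    grads[[paste0(key, ".bn2.gamma")]] <- bb2$dgamma
    grads[[paste0(key, ".bn2.beta")]] <- bb2$dbeta
    cb2 <- cpp_conv2d_bwd(cc$r1, p[[paste0(key, ".conv2")]], bb2$dx,
                          3L, 3L, 1L, 1L, TRUE)
    grads[[paste0(key, ".conv2")]] <- cb2$dw
    dr1 <- cpp_relu_bwd(cb2$dx, cc$r1)
    bb1 <- cpp_bn_bwd(cc$c1, dr1, p[[paste0(key, ".bn1.gamma")]],
                      cc$m1, cc$i1)
    grads[[paste0(key, ".bn1.gamma")]] <- bb1$dgamma
    grads[[paste0(key, ".bn1.beta")]] <- bb1$dbeta
    cb1 <- cpp_conv2d_bwd(cc$xin, p[[paste0(key, ".conv1")]], bb1$dx,
                          3L, 3L, bl$stride, 1L, TRUE)
    grads[[paste0(key, ".conv1")]] <- cb1$dw
    if (bl$down) {
      bbd <- cpp_bn_bwd(cc$cd, ds, p[[paste0(key, ".down.bn.gamma")]],
                        cc$md, cc$id)
      grads[[paste0(key, ".down.bn.gamma")]] <- bbd$dgamma
      grads[[paste0(key, ".down.bn.beta")]] <- bbd$dbeta
      cbd <- cpp_conv2d_bwd(cc$xin, p[[paste0(key, ".down.conv")]],
                            bbd$dx, 1L, 1L, bl$stride, 0L, TRUE)
      grads[[paste0(key, ".down.conv")]] <- cbd$dw
      dout <- cb1$dx + cbd$dx
    } else {
      dout <- cb1$dx + ds
    }
  }

  dpoolin <- cpp_maxpool_bwd(dout, cache$stem$poolIdx, cache$stem$poolDim)
  dbny <- cpp_relu_bwd(dpoolin, cache$stem$bny)
  bbs <- cpp_bn_bwd(cache$stem$conv, dbny, p[["stem.bn.gamma"]],
                    cache$stem$mean, cache$stem$invstd)
  grads[["stem.bn.gamma"]] <- bbs$dgamma
  grads[["stem.bn.beta"]] <- bbs$dbeta
  cbs <- cpp_conv2d_bwd(cache$x, p[["stem.conv"]], bbs$dx, 7L, 7L, 2L,
                        3L, FALSE)
  grads[["stem.conv"]] <- cbs$dw
  grads
}

# Activation shapes of the forward pass (fidelity audit).
#' Trace activation shapes
#'
#' @param spec an [archSpec()].
#' @param batchSize batch size used in the shape report.
#' @return data.frame of `(layer, channels, height, width)` after each
#'   named module.
#' @export
traceShapes <- function(spec, batchSize = 64) {
  convOut <- function(inSize, k, s, p) (inSize + 2 * p - k) %/% s + 1
  rows <- list()
  s <- convOut(spec$inputSize, 7, 2, 3)
  rows[["stem.conv"]] <- c(spec$widths[1], s, s)
  s <- convOut(s, 3, 2, 1)
  rows[["stem.pool"]] <- c(spec$widths[1], s, s)
  for (key in names(.layerPlan(spec))) {
    bl <- .layerPlan(spec)[[key]]
    s <- convOut(s, 3, bl$stride, 1)
    rows[[key]] <- c(bl$outC, s, s)
  }
  rows[["gap"]] <- c(spec$widths[4], 1, 1)
  rows[["fc"]] <- c(1, 1, 1)
  out <- do.call(rbind, rows)
  data.frame(layer = rownames(out), batch = batchSize,
             channels = out[, 1], height = out[, 2], width = out[, 3],
             row.names = NULL)
}
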