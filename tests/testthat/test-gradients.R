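# Finite-difference verification of the network engine's gradients.

test_that("analytic gradients match central differences through the full network", {
  spec <- archSpec(32, 2 / 64)
  net <- buildNetwork(spec, seed = 7)
  set.seed(3)
  x <- array(runif(32 * 32 * 3), c(32, 32, 1, 3))
  y <- c(0, 1, 1)
  fw <- SpectCertainty:::.nnForward
  bw <- SpectCertainty:::.nnBackward
  lossGrad <- SpectCertainty:::.lossGrad

  for (loss in c("bce", "mse")) {
    f <- fw(net, x, training = TRUE)
    lg <- lossGrad(f$z, if (loss == "mse") c(0, 1 / 3, 1) else y, loss)
    g <- bw(net, f$cache, lg$dz)
    snap <- as.list(net@env$state)
    reset <- function() for (k in names(snap)) net@env$state[[k]] <- snap[[k]]
    lossAt <- function() {
      reset()
      z <- fw(net, x, training = TRUE)$z
      lossGrad(z, if (loss == "mse") c(0, 1 / 3, 1) else y, loss)$value
    }
    set.seed(17)
    for (nm in sample(names(g), 8)) {
      i <- sample(length(net@env$params[[nm]]), 1)
      p0 <- net@env$params[[nm]][i]
      eps <- 1e-4
      net@env$params[[nm]][i] <- p0 + eps
      lp <- lossAt()
      net@env$params[[nm]][i] <- p0 - eps
      lm <- lossAt()
      net@env$params[[nm]][i] <- p0
      reset()
      num <- (lp - lm) / (2 * eps)
      ana <- g[[nm]][i]
      # single-precision forward limits the attainable agreement
      expect_lt(abs(num - ana), 0.05 * max(0.02, abs(num) + abs(ana)))
    }
  }
})

test_that("inference is deterministic and batch-size invariant", {
  net <- buildNetwork(archSpec(32, 2 / 64), seed = 1)
  set.seed(2)
  x <- array(runif(32 * 32 * 6), c(32, 32, 1, 6))
  z1 <- SpectCertainty:::.nnForward(net, x)$z
  z2 <- SpectCertainty:::.nnForward(net, x)$z
  expect_identical(z1, z2)
  # evaluation-mode batch norm makes per-case outputs independent
  za <- SpectCertainty:::.nnForward(net, x[, , , 1:2, drop = FALSE])$z
  expect_equal(z1[1:2], za, tolerance = 1e-5)
})
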