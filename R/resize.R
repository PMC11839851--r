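# Bicubic interpolation (Keys kernel, a = -0.5).  Separable: the resize
# is two dense matrix products with precomputed 1-D weight matrices.
# Edge samples are clamped, and the kernel's partition of unity keeps
# constant images exactly constant.

.cubicKernel <- function(d, a = -0.5) {
  d <- abs(d)
  ifelse(d <= 1, (a + 2) * d^3 - (a + 3) * d^2 + 1,
         ifelse(d < 2, a * d^3 - 5 * a * d^2 + 8 * a * d - 4 * a, 0))
}

.resizeWeights <- function(src, target) {
  w <- matrix(0, target, src)
  scale <- src / target
  for (i in seq_len(target)) {
    center <- (i - 0.5) * scale + 0.5   # 1-based source coordinate
    base <- floor(center)
    for (j in (base - 1):(base + 2)) {
      wt <- .cubicKernel(center - j)
      jc <- min(max(j, 1), src)         # clamp at the borders
      w[i, jc] <- w[i, jc] + wt
    }
  }
  w
}

#' Resize an image by bicubic interpolation
#'
#' @param img numeric matrix.
#' @param target output side length in pixels (output is
#'   `target x target`).
#' @return the resized matrix.
#' @examples
#' resizeBicubic(matrix(1, 8, 8), 16)[1, 1]  # exactly 1
#' @export
resizeBicubic <- function(img, target) {
  if (!is.matrix(img)) stop("img must be a matrix")
  if (length(target) != 1 || target <= 0)
    stop("target must be a positive integer")
  wr <- .resizeWeights(nrow(img), target)
  wc <- .resizeWeights(ncol(img), target)
  wr %*% img %*% t(wc)
}
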