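# Small separable filtering helpers shared by the segmentation backends.
# Borders are handled by symmetric reflection (border pixel included), the
# repo-wide padding rule, so no spurious frame edges appear.

# reflected index vector of length n + 2k
.reflectIdx <- function(n, k) {
  if (k == 0) return(seq_len(n))
  c(pmin(k:1, n), seq_len(n), pmax(n - 0:(k - 1), 1))
}

# 1-D correlation along columns (x direction) with reflect padding
.convCols <- function(m, w) {
  k <- (length(w) - 1L) / 2L
  p <- m[, .reflectIdx(ncol(m), k), drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(w))
    out <- out + w[i] * p[, (i - 1L) + seq_len(ncol(m)), drop = FALSE]
  out
}

# 1-D correlation along rows (y direction) with reflect padding
.convRows <- function(m, w) {
  k <- (length(w) - 1L) / 2L
  p <- m[.reflectIdx(nrow(m), k), , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(w))
    out <- out + w[i] * p[(i - 1L) + seq_len(nrow(m)), , drop = FALSE]
  out
}

# normalized 1-D Gaussian taps
.gaussKernel <- function(ksize, sigma) {
  stopifnot(ksize %% 2 == 1, ksize >= 1, sigma > 0)
  x <- seq(-(ksize - 1L) / 2L, (ksize - 1L) / 2L)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# separable Gaussian smoothing
.gaussianBlur <- function(m, ksize, sigma) {
  w <- .gaussKernel(ksize, sigma)
  .convRows(.convCols(m, w), w)
}

# shift a matrix by (dx, dy) pixels with reflect padding at the borders
.shiftMat <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dy, 1), nr)
  ci <- pmin(pmax(seq_len(nc) + dx, 1), nc)
  m[ri, ci, drop = FALSE]
}

# local block mean via separable box filter with reflect padding
.boxMean <- function(m, block) {
  w <- rep(1 / block, block)
  .convRows(.convCols(m, w), w)
}
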