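#' Convolution block forward pass
#'
#' 'Same'-padded stride-1 2D cross-correlation over a stack of input feature
#' maps followed by ReLU: `relu(b_j + sum_i w_ij * x_i)` for each output map
#' j. This is the conv + activation part of one network module.
#'
#' @param x input feature map, `H x W x Cin` array (or `H x W` matrix for a
#'   single map).
#' @param w kernels, `kh x kw x Cin x Cout` array with odd `kh`, `kw`.
#' @param b bias vector, length `Cout`.
#' @param activation `"relu"` (default) or `"linear"`.
#' @return `H x W x Cout` array.
#' @export
conv_block_forward <- function(x, w, b, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1)
  stopifnot(length(dim(x)) == 3, length(dim(w)) == 4)
  if (dim(x)[3] != dim(w)[3])
    stop("input has ", dim(x)[3], " maps but kernel expects ", dim(w)[3])
  x4 <- x; dim(x4) <- c(dim(x), 1)
  y <- cpp_conv2d_forward(x4, w, as.numeric(b))
  dim(y) <- dim(y)[1:3]
  if (activation == "relu") y <- pmax(y, 0)
  y
}

#' Batch normalization forward pass
#'
#' Normalizes each feature over the mini-batch, then rescales:
#' `(x - mean) / sqrt(var + eps) * gamma + beta`. Training mode uses the
#' batch statistics (and requires batch size >= 2); inference mode uses the
#' supplied running statistics.
#'
#' @param x numeric matrix, batch x features.
#' @param gamma,beta learned scale and shift, length = features.
#' @param eps numerical stabilizer (default 1e-5).
#' @param training logical; batch statistics (TRUE) vs running statistics.
#' @param run_mean,run_var running statistics, required when
#'   `training = FALSE`.
#' @return Matrix of the same shape as `x`.
#' @export
batchnorm_forward <- function(x, gamma, beta, eps = 1e-5, training = TRUE,
                              run_mean = NULL, run_var = NULL) {
  x <- as.matrix(x)
  if (training) {
    if (nrow(x) < 2)
      stop("batch normalization in training mode requires batch size >= 2")
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2            # biased (population) variance
  } else {
    if (is.null(run_mean) || is.null(run_var))
      stop("inference mode requires running statistics")
    mu <- run_mean; v <- run_var
  }
  xhat <- sweep(sweep(x, 2, mu, "-"), 2, sqrt(v + eps), "/")
  sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
}

#' Max-pooling forward pass
#'
#' 2 x 2 window, stride 2 (the only pooling the network uses): each output
#' cell is the maximum of its window; spatial dimensions halve.
#'
#' @param x `H x W x C` array (or `H x W` matrix) with even `H`, `W`.
#' @return `(H/2) x (W/2) x C` array (matrix in, matrix out).
#' @export
maxpool_forward <- function(x) {
  was_mat <- length(dim(x)) == 2
  if (was_mat) dim(x) <- c(dim(x), 1)
  x4 <- x; dim(x4) <- c(dim(x), 1)
  y <- cpp_maxpool_forward(x4)$y
  dim(y) <- dim(y)[1:3]
  if (was_mat) dim(y) <- dim(y)[1:2]
  y
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Channel attention weights
#'
#' The 'what to attend to' half of the attention block: global average-pool
#' and global max-pool the feature map over space, push both pooled vectors
#' through a shared two-layer bottleneck MLP (ReLU in between), add, and
#' squash: `sigma(M1 relu(M0 f_avg) + M1 relu(M0 f_max))`.
#'
#' @param f `H x W x C` feature map.
#' @param M0 bottleneck weights, `(C/r) x C`.
#' @param M1 expansion weights, `C x (C/r)`.
#' @return Length-`C` weight vector, each entry in (0, 1).
#' @export
channel_attention <- function(f, M0, M1) {
  stopifnot(length(dim(f)) == 3)
  C <- dim(f)[3]
  if (ncol(M0) != C || nrow(M1) != C || nrow(M0) != ncol(M1))
    stop("MLP weight shapes inconsistent with ", C, " channels")
  m <- matrix(f, ncol = C)
  v_avg <- colMeans(m)
  v_max <- apply(m, 2, max)
  a <- M1 %*% pmax(M0 %*% v_avg, 0) + M1 %*% pmax(M0 %*% v_max, 0)
  as.numeric(sigmoid(a))
}

#' Spatial attention map
#'
#' The 'where to attend' half: average and max over the channel axis give two
#' `H x W` planes; a same-padded 7 x 7 convolution over the 2-plane stack,
#' squashed by a sigmoid, yields one weight per spatial position.
#'
#' @param f `H x W x C` feature map.
#' @param w7 convolution kernel, `7 x 7 x 2 x 1` array.
#' @param b7 scalar bias (default 0).
#' @return `H x W` matrix of weights in (0, 1).
#' @export
spatial_attention <- function(f, w7, b7 = 0) {
  stopifnot(length(dim(f)) == 3, all(dim(w7) == c(7, 7, 2, 1)))
  H <- dim(f)[1]; W <- dim(f)[2]; C <- dim(f)[3]
  m <- matrix(f, nrow = H * W)
  planes <- array(c(rowMeans(m), apply(m, 1, function(r) max(r))),
                  dim = c(H, W, 2))
  z <- conv_block_forward(planes, w7, b7, activation = "linear")
  sigmoid(matrix(z, H, W))
}

#' Apply the convolutional block attention module
#'
#' Sequentially applies channel then spatial attention, each multiplicatively:
#' `F_c = M_c(F) (x) F`, then `F_s = M_s(F_c) (x) F_c`. Since every weight is
#' in (0, 1), the output is element-wise no larger in magnitude than the
#' input.
#'
#' @param f `H x W x C` feature map.
#' @param params list with elements `M0`, `M1` (channel MLP), `w7`, `b7`
#'   (spatial convolution).
#' @return Attended feature map, same shape as `f`.
#' @export
cbam_apply <- function(f, params) {
  mc <- channel_attention(f, params$M0, params$M1)
  fc <- f * rep(mc, each = prod(dim(f)[1:2]))
  ms <- spatial_attention(fc, params$w7, params$b7 %||% 0)
  fc * as.vector(ms)    # (H*W) weights recycle over channels
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label smoothing
#'
#' Softens hard training targets: `y' = (1 - eps) * y`. As printed this is
#' asymmetric — a negative label stays exactly 0 while a positive label
#' becomes `1 - eps`. A `symmetric` option (`y' = y (1 - eps) + (1 - y) eps`)
#' is provided for comparison but is off by default.
#'
#' @param y numeric vector of labels in `{0, 1}`.
#' @param eps smoothing parameter in `[0, 1)` (the reference setting is 0.1).
#' @param symmetric use the symmetric variant (default `FALSE`).
#' @return Smoothed targets.
#' @export
smooth_labels <- function(y, eps = 0.1, symmetric = FALSE) {
  if (eps < 0 || eps >= 1) stop("eps must be in [0, 1)")
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  if (symmetric) y * (1 - eps) + (1 - y) * eps else (1 - eps) * y
}

#' Label-smoothed binary cross-entropy
#'
#' `-(1/N) sum[y' log p + (1 - y') log(1 - p)]`, with predictions clamped to
#' `[1e-7, 1 - 1e-7]` for numerical stability.
#'
#' @param p predicted error-class probabilities.
#' @param y_smooth (smoothed) targets, same length.
#' @return Scalar mean loss.
#' @export
smoothed_bce <- function(p, y_smooth) {
  stopifnot(length(p) == length(y_smooth))
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y_smooth * log(p) + (1 - y_smooth) * log(1 - p))
}
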