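# Independent nested-loop oracles for the network equations, plus small
# fixture builders. These deliberately avoid the package's vectorized /
# compiled code paths.

# 'same'-padded stride-1 cross-correlation: y_j = b_j + sum_i w_ij * x_i
loop_conv <- function(x, w, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  y <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) for (h in seq_len(H)) for (wd in seq_len(W)) {
    s <- b[co]
    for (ci in seq_len(Cin)) for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
      hh <- h + ki - 1 - ph; ww <- wd + kj - 1 - pw
      if (hh >= 1 && hh <= H && ww >= 1 && ww <= W)
        s <- s + w[ki, kj, ci, co] * x[hh, ww, ci]
    }
    y[h, wd, co] <- s
  }
  y
}

# mini-batch normalization, one feature at a time
loop_bn <- function(x, gamma, beta, eps) {
  y <- x
  for (k in seq_len(ncol(x))) {
    mu <- mean(x[, k])
    v <- mean((x[, k] - mu)^2)
    y[, k] <- (x[, k] - mu) / sqrt(v + eps) * gamma[k] + beta[k]
  }
  y
}

# exhaustive 2x2/stride-2 window maximum
loop_pool <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  y <- array(0, c(H / 2, W / 2, C))
  for (c in seq_len(C)) for (i in seq_len(H / 2)) for (j in seq_len(W / 2))
    y[i, j, c] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c])
  y
}

# channel attention, scalar loops: sigma(M1 relu(M0 favg) + M1 relu(M0 fmax))
loop_channel_attention <- function(f, M0, M1) {
  C <- dim(f)[3]
  favg <- fmax <- numeric(C)
  for (c in seq_len(C)) {
    favg[c] <- mean(f[, , c])
    fmax[c] <- max(f[, , c])
  }
  mlp <- function(v) {
    h <- numeric(nrow(M0))
    for (i in seq_len(nrow(M0))) h[i] <- max(sum(M0[i, ] * v), 0)
    o <- numeric(nrow(M1))
    for (i in seq_len(nrow(M1))) o[i] <- sum(M1[i, ] * h)
    o
  }
  1 / (1 + exp(-(mlp(favg) + mlp(fmax))))
}

# spatial attention, scalar loops over the 7x7 window
loop_spatial_attention <- function(f, w7, b7 = 0) {
  H <- dim(f)[1]; W <- dim(f)[2]; C <- dim(f)[3]
  avg <- apply(f, c(1, 2), mean)
  mx <- apply(f, c(1, 2), max)
  planes <- array(c(avg, mx), c(H, W, 2))
  z <- loop_conv(planes, w7, b7)[, , 1]
  1 / (1 + exp(-z))
}

# small architecture for fast training tests (32x32 input)
tiny_spec <- function(dropout = 0.5)
  atcnn_spec(input_size = 32, filters = c(2, 3, 2, 4), r = 2, fc = c(6, 4),
             dropout = dropout)

# separable 32x32 image set: class 1 has a dark band in the upper half,
# class 0 in the lower half, plus salt noise
tiny_images <- function(n, seed = 1) {
  set.seed(seed)
  y <- rep_len(c(0L, 1L), n)
  x <- array(1, c(32, 32, n))
  for (i in seq_len(n)) {
    r0 <- if (y[i] == 1) 6 else 22
    x[r0:(r0 + 3), , i] <- 0
    x[cbind(sample(32, 20, TRUE), sample(32, 20, TRUE), i)] <- 0
  }
  list(x = x, y = y)
}

# epoch set whose labels are decodable from the rendered image: error trials
# rise 0 -> 1, correct trials fall 1 -> 0 (used to build oracle base models)
decodable_epochs <- function(n, channels = c("FCZ", "CZ"), rate = 64,
                             seed = 1) {
  set.seed(seed)
  y <- stats::rbinom(n, 1, 0.5)
  ns <- rate                                   # 1 s window
  data <- array(0, c(n, length(channels), ns))
  for (i in seq_len(n)) {
    tr <- seq(0, 1, length.out = ns)
    if (y[i] == 0) tr <- rev(tr)
    for (ch in seq_along(channels)) data[i, ch, ] <- tr
  }
  eeg_epochs(data, y, rate = rate, window = c(-0.2, 0.8),
             channel_names = channels, normalized = TRUE)
}

# base-model stand-in that decodes the label from a decodable_epochs image:
# rising trace => trace pixel in the top rows of the last column
oracle_trainer <- function(images, labels, config, spec) {
  structure(list(), class = "img_oracle")
}
oracle_predictor <- function(model, images) {
  n <- dim(images)[3]
  out <- integer(n)
  for (i in seq_len(n)) {
    img <- images[, , i]
    last_col <- which(img[, ncol(img)] == 0)
    first_col <- which(img[, 1] == 0)
    out[i] <- as.integer(min(last_col) < min(first_col))  # ends higher up
  }
  out
}
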