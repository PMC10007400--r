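#' Attention CNN architecture specification
#'
#' Describes the 2D-image classifier: four conv modules
#' (conv 3x3 / ReLU / batch-norm / 2x2 max-pool, widths 8-16-32-64), a
#' convolutional block attention module after the last pool, then
#' fully-connected layers 12544 -> 896 -> 64 -> 2 with ReLU + dropout and a
#' softmax head. The spatial chain for a 224 x 224 x 1 input is
#' 112^2 x 8, 56^2 x 16, 28^2 x 32, 14^2 x 64, flatten length 12544; the
#' chain is computed and checked at construction.
#'
#' @param input_size input image side in pixels (default 224); must be
#'   divisible by `2^length(filters)`.
#' @param filters conv widths per module (default `c(8, 16, 32, 64)`).
#' @param kernel conv kernel side (default 3, 'same' padding).
#' @param r channel-attention reduction ratio; must divide the last conv
#'   width (default 16, i.e. bottleneck 4 at width 64; the source
#'   architecture leaves r unstated).
#' @param fc hidden fully-connected sizes (default `c(896, 64)`).
#' @param dropout dropout rate after each hidden FC layer (default 0.5; none
#'   after the output layer).
#' @param eps_bn batch-norm stabilizer (default 1e-5).
#' @return An object of class `atcnn_spec` with a `shapes` element listing
#'   the module-by-module output shapes.
#' @export
#' @examples
#' s <- atcnn_spec()
#' s$flatten  # 12544
atcnn_spec <- function(input_size = 224, filters = c(8, 16, 32, 64),
                       kernel = 3, r = 16, fc = c(896, 64), dropout = 0.5,
                       eps_bn = 1e-5) {
  n_mod <- length(filters)
  if (input_size %% 2^n_mod != 0)
    stop("input_size must be divisible by ", 2^n_mod)
  if (kernel %% 2 != 1) stop("kernel must be odd (same padding)")
  C <- filters[n_mod]
  if (C %% r != 0) stop("reduction ratio r must divide the last conv width")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  side <- input_size
  shapes <- list(input = c(side, side, 1))
  for (m in seq_len(n_mod)) {
    shapes[[paste0("conv", m)]] <- c(side, side, filters[m])
    side <- side / 2
    shapes[[paste0("pool", m)]] <- c(side, side, filters[m])
  }
  flatten <- side^2 * C
  shapes$cbam <- c(side, side, C)
  shapes$flatten <- flatten
  spec <- structure(list(input_size = input_size, filters = filters,
                         kernel = kernel, r = r, fc = fc, dropout = dropout,
                         eps_bn = eps_bn, flatten = flatten, shapes = shapes),
                    class = "atcnn_spec")
  # canonical-architecture sanity check
  if (input_size == 224 && identical(filters, c(8, 16, 32, 64)) &&
      flatten != 12544)
    stop("internal error: canonical shape chain violated")
  spec
}

#' @export
print.atcnn_spec <- function(x, ...) {
  cat("<atcnn_spec>\n")
  for (nm in names(x$shapes))
    cat(sprintf("  %-8s %s\n", nm, paste(x$shapes[[nm]], collapse = " x ")))
  cat(sprintf("  fc       %s\n",
              paste(c(x$flatten, x$fc, 2), collapse = " -> ")))
  cat(sprintf("  CBAM r = %d, dropout = %g\n", x$r, x$dropout))
  invisible(x)
}

# He-initialized parameters; running BN statistics start at (0, 1).
atcnn_init <- function(spec, seed = 1) {
  set.seed(seed)
  he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
  p <- list(); s <- list()
  Cin <- 1
  for (m in seq_along(spec$filters)) {
    Cout <- spec$filters[m]
    k <- spec$kernel
    p[[paste0("cw", m)]] <- array(he(k * k * Cin, k * k * Cin * Cout),
                                  dim = c(k, k, Cin, Cout))
    p[[paste0("cb", m)]] <- numeric(Cout)
    p[[paste0("g", m)]] <- rep(1, Cout)
    p[[paste0("be", m)]] <- numeric(Cout)
    s[[paste0("rm", m)]] <- numeric(Cout)
    s[[paste0("rv", m)]] <- rep(1, Cout)
    Cin <- Cout
  }
  s$bn_t <- 0L       # BN running-average update count (for debiasing)
  C <- Cin; h <- C %/% spec$r
  p$M0 <- matrix(he(C, h * C), h, C)
  p$M1 <- matrix(he(h, C * h), C, h)
  p$w7 <- array(he(7 * 7 * 2, 7 * 7 * 2), dim = c(7, 7, 2, 1))
  p$b7 <- 0
  sizes <- c(spec$flatten, spec$fc, 2)
  for (j in seq_len(length(sizes) - 1)) {
    p[[paste0("fW", j)]] <- matrix(he(sizes[j], sizes[j + 1] * sizes[j]),
                                   sizes[j + 1], sizes[j])
    p[[paste0("fb", j)]] <- numeric(sizes[j + 1])
  }
  list(params = p, state = s)
}

#' Construct an (untrained) attention CNN
#'
#' @param spec an [atcnn_spec()] (default: the canonical 224 x 224
#'   architecture).
#' @param seed seed for weight initialization.
#' @return An object of class `atcnn` (untrained; see [train_atcnn()]).
#' @export
atcnn <- function(spec = atcnn_spec(), seed = 1) {
  stopifnot(inherits(spec, "atcnn_spec"))
  init <- atcnn_init(spec, seed)
  structure(list(spec = spec, params = init$params, state = init$state,
                 history = NULL, trained = FALSE),
            class = "atcnn")
}

# ---- batched forward / backward --------------------------------------------

# per-channel sums over (H, W, N) of a (H, W, C, N) array
.csum <- function(a, HW, C) rowSums(matrix(colSums(matrix(a, HW)), C))

channel_stats <- function(x) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  s1 <- .csum(x, HW, C); s2 <- .csum(x * x, HW, C)
  m <- s1 / (HW * N)
  list(mean = m, var = pmax(s2 / (HW * N) - m^2, 0))
}

cbam_forward_batch <- function(pars, x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]; HW <- H * W
  m <- matrix(x, HW)                              # HW x (C*N)
  Vavg <- matrix(colMeans(m), C)                  # C x N
  amax <- max.col(t(m), ties.method = "first")
  Vmax <- matrix(m[cbind(amax, seq_len(C * N))], C)
  Havg <- pmax(pars$M0 %*% Vavg, 0)
  Hmax <- pmax(pars$M0 %*% Vmax, 0)
  Mc <- sigmoid(pars$M1 %*% Havg + pars$M1 %*% Hmax)   # C x N
  fc <- x * rep(as.vector(Mc), each = HW)
  perm <- aperm(fc, c(1, 2, 4, 3))                # (H, W, N, C)
  pm <- matrix(perm, ncol = C)                    # (HW*N) x C
  smax <- max.col(pm, ties.method = "first")
  P <- array(0, dim = c(H, W, 2, N))
  P[, , 1, ] <- array(rowMeans(pm), dim = c(H, W, N))
  P[, , 2, ] <- array(pm[cbind(seq_len(HW * N), smax)], dim = c(H, W, N))
  z <- cpp_conv2d_forward(P, pars$w7, pars$b7)
  S3 <- sigmoid(array(z, dim = c(H, W, N)))
  Sexp <- aperm(array(as.vector(S3), dim = c(H, W, N, C)), c(1, 2, 4, 3))
  list(out = fc * Sexp,
       cache = list(x = x, Mc = Mc, fc = fc, amax = amax, smax = smax,
                    Havg = Havg, Hmax = Hmax, Vavg = Vavg, Vmax = Vmax,
                    P = P, S3 = S3, Sexp = Sexp))
}

cbam_backward_batch <- function(pars, cache, dFs) {
  d <- dim(cache$x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]; HW <- H * W
  dfc <- dFs * cache$Sexp
  tmp <- aperm(dFs * cache$fc, c(1, 2, 4, 3))
  dS3 <- rowSums(matrix(tmp, ncol = C))                       # HW*N
  s3v <- as.vector(cache$S3)
  dz <- array(dS3 * s3v * (1 - s3v), dim = c(H, W, 1, N))
  cb <- cpp_conv2d_backward(cache$P, pars$w7, dz)
  dP <- cb$dx
  dA3 <- as.vector(dP[, , 1, ])
  sc <- matrix(0, HW * N, C)
  sc[cbind(seq_len(HW * N), cache$smax)] <- as.vector(dP[, , 2, ])
  sc <- sc + dA3 / C
  dfc <- dfc + aperm(array(sc, dim = c(H, W, N, C)), c(1, 2, 4, 3))
  # channel-attention backward
  dx <- dfc * rep(as.vector(cache$Mc), each = HW)
  dMc <- matrix(colSums(matrix(dfc * cache$x, HW)), C)        # C x N
  dA <- dMc * cache$Mc * (1 - cache$Mc)
  dHavg <- (t(pars$M1) %*% dA) * (cache$Havg > 0)
  dHmax <- (t(pars$M1) %*% dA) * (cache$Hmax > 0)
  dM1 <- dA %*% t(cache$Havg) + dA %*% t(cache$Hmax)
  dM0 <- dHavg %*% t(cache$Vavg) + dHmax %*% t(cache$Vmax)
  dVavg <- t(pars$M0) %*% dHavg
  dVmax <- t(pars$M0) %*% dHmax
  dx <- dx + rep(as.vector(dVavg) / HW, each = HW)
  dxm <- matrix(dx, HW)
  idx <- cbind(cache$amax, seq_len(C * N))
  dxm[idx] <- dxm[idx] + as.vector(dVmax)
  list(dx = array(dxm, dim = d), dM0 = dM0, dM1 = dM1,
       dw7 = cb$dw, db7 = cb$db)
}

# Forward pass over a batch. x: (H, W, N) images in [0, 1].
# Returns error-class probabilities; with keep_cache = TRUE also everything
# the backward pass needs. Dropout masks are drawn from the current RNG.
nn_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  spec <- model$spec; p <- model$params; st <- model$state
  d <- dim(x); N <- d[3]
  if (d[1] != spec$input_size || d[2] != spec$input_size)
    stop("input images must be ", spec$input_size, " x ", spec$input_size)
  if (training && N < 2)
    stop("training-mode forward needs a batch of >= 2 (batch norm)")
  a <- array(x, dim = c(d[1], d[2], 1, N))
  mods <- vector("list", length(spec$filters))
  batch_stats <- vector("list", length(spec$filters))
  for (m in seq_along(spec$filters)) {
    inp <- a
    z <- cpp_conv2d_forward(inp, p[[paste0("cw", m)]], p[[paste0("cb", m)]])
    z[z < 0] <- 0                                   # ReLU
    if (training) {
      stt <- cpp_channel_stats(z)
      batch_stats[[m]] <- stt
    } else {
      # debias the exponential moving averages (initialized at mean 0, var 1)
      tbn <- st$bn_t %||% 0L
      if (tbn > 0) {
        corr <- 1 - 0.9^tbn
        stt <- list(mean = st[[paste0("rm", m)]] / corr,
                    var = pmax((st[[paste0("rv", m)]] - 0.9^tbn) / corr, 0))
      } else {
        stt <- list(mean = st[[paste0("rm", m)]], var = st[[paste0("rv", m)]])
      }
    }
    bnf <- cpp_bn_forward(z, stt$mean, stt$var, p[[paste0("g", m)]],
                          p[[paste0("be", m)]], spec$eps_bn)
    pl <- cpp_maxpool_forward(bnf$y)
    if (keep_cache)
      mods[[m]] <- list(inp = inp, relu = z, xhat = bnf$xhat,
                        invstd = bnf$invstd, argmax = pl$argmax,
                        ydim = dim(bnf$y))
    a <- pl$y
  }
  cb <- cbam_forward_batch(p, a)
  X0 <- matrix(cb$out, nrow = spec$flatten)
  acts <- list(X0)
  drops <- list()
  nfc <- length(spec$fc) + 1
  A <- X0
  for (j in seq_len(nfc)) {
    Z <- p[[paste0("fW", j)]] %*% A + p[[paste0("fb", j)]]
    if (j < nfc) {
      A <- pmax(Z, 0)
      if (training && spec$dropout > 0) {
        mask <- matrix(stats::rbinom(length(A), 1, 1 - spec$dropout),
                       nrow(A)) / (1 - spec$dropout)
        A <- A * mask
        drops[[j]] <- mask
      }
      acts[[j + 1]] <- A
    } else {
      Z <- sweep(Z, 2, apply(Z, 2, max), "-")       # stable softmax
      E <- exp(Z)
      prob <- sweep(E, 2, colSums(E), "/")          # 2 x N; row 2 = error
    }
  }
  out <- list(prob = prob[2, ], prob2 = prob)
  if (keep_cache)
    out$cache <- list(mods = mods, cbam = cb$cache, acts = acts,
                      drops = drops, prob2 = prob, batch_stats = batch_stats)
  out
}

# Backward pass for the label-smoothed BCE on the error-class probability.
# Returns gradients named like the trainable parameters.
nn_backward <- function(model, cache, y_smooth) {
  spec <- model$spec; p <- model$params
  g <- list()
  prob <- cache$prob2
  pe <- pmin(pmax(prob[2, ], 1e-7), 1 - 1e-7)
  N <- length(pe)
  dLdp <- -(y_smooth / pe - (1 - y_smooth) / (1 - pe)) / N
  dlog2 <- dLdp * pe * (1 - pe)                    # through 2-way softmax
  dZ <- rbind(-dlog2, dlog2)
  nfc <- length(spec$fc) + 1
  for (j in rev(seq_len(nfc))) {
    A_prev <- cache$acts[[j]]
    g[[paste0("fW", j)]] <- tcrossprod(dZ, A_prev)
    g[[paste0("fb", j)]] <- rowSums(dZ)
    dA <- crossprod(p[[paste0("fW", j)]], dZ)
    if (j > 1) {
      if (length(cache$drops) >= j - 1 && !is.null(cache$drops[[j - 1]]))
        dA <- dA * cache$drops[[j - 1]]
      dZ <- dA * (cache$acts[[j]] > 0)
    }
  }
  side <- spec$input_size / 2^length(spec$filters)
  dFs <- array(dA, dim = c(side, side, spec$filters[length(spec$filters)], N))
  cbg <- cbam_backward_batch(p, cache$cbam, dFs)
  g$M0 <- cbg$dM0; g$M1 <- cbg$dM1; g$w7 <- cbg$dw7; g$b7 <- cbg$db7
  dpool <- cbg$dx
  for (m in rev(seq_along(spec$filters))) {
    mc <- cache$mods[[m]]
    dy <- cpp_maxpool_backward(dpool, mc$argmax, mc$ydim)
    bnb <- cpp_bn_backward(dy, mc$xhat, mc$invstd, p[[paste0("g", m)]],
                           mc$relu)               # fused ReLU mask
    g[[paste0("g", m)]] <- bnb$dgamma
    g[[paste0("be", m)]] <- bnb$dbeta
    cv <- cpp_conv2d_backward(mc$inp, p[[paste0("cw", m)]], bnb$dx)
    g[[paste0("cw", m)]] <- cv$dw
    g[[paste0("cb", m)]] <- cv$db
    dpool <- cv$dx
  }
  g
}

#' Forward pass of the attention CNN on one image
#'
#' @param img an `eeg_image` (integer 0/255 matrix) or numeric matrix in
#'   `[0, 1]`, sized to the model's input.
#' @param model an `atcnn` object.
#' @param threshold hard-label threshold on the error-class probability
#'   (default 0.5).
#' @return A list with `p` (error-class probability), `hard_label` (0/1) and
#'   `prob` (both softmax outputs, summing to 1).
#' @export
atcnn_forward <- function(img, model, threshold = 0.5) {
  stopifnot(inherits(model, "atcnn"))
  x <- as.numeric(img)
  if (max(x) > 1) x <- x / 255
  x <- array(x, dim = c(nrow(img), ncol(img), 1))
  fw <- nn_forward(model, x, training = FALSE)
  list(p = fw$prob[1], hard_label = as.integer(fw$prob[1] >= threshold),
       prob = fw$prob2[, 1])
}

#' Predict from a trained attention CNN
#'
#' @param object an `atcnn` model.
#' @param newdata a list of images (as from [render_epochs()]) or an
#'   `H x W x N` array.
#' @param type `"class"` (default) for hard 0/1 labels or `"prob"` for
#'   error-class probabilities.
#' @param threshold hard-label threshold (default 0.5).
#' @param batch_size forward-pass batch size (default 64).
#' @param backend `"cpp"` (default, fast single-precision engine) or `"R"`
#'   (double-precision reference path).
#' @param ... unused.
#' @return Numeric vector of labels or probabilities, one per image.
#' @export
predict.atcnn <- function(object, newdata, type = c("class", "prob"),
                          threshold = 0.5, batch_size = 64,
                          backend = c("cpp", "R"), ...) {
  type <- match.arg(type)
  backend <- match.arg(backend)
  x <- if (is.list(newdata)) images_to_array(newdata) else newdata
  if (max(x) > 1) x <- x / 255
  N <- dim(x)[3]
  if (backend == "cpp") {
    ptr <- cpp_trainer_create(object$params, unclass(object$spec),
                              as.integer(min(N, batch_size)))
    cpp_trainer_set_params(ptr, object$params, object$state)
    probs <- ptr_predict(ptr, x, as.integer(min(N, batch_size)))
  } else {
    probs <- numeric(N)
    for (s in seq(1, N, by = batch_size)) {
      idx <- s:min(s + batch_size - 1, N)
      probs[idx] <- nn_forward(object, x[, , idx, drop = FALSE])$prob
    }
  }
  if (type == "prob") probs else as.integer(probs >= threshold)
}

#' @export
print.atcnn <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<atcnn> %s, %s parameters\n",
              if (x$trained) "trained" else "untrained",
              format(np, big.mark = ",")))
  cat(sprintf("  input %d x %d, conv widths %s, CBAM r = %d, fc %s\n",
              x$spec$input_size, x$spec$input_size,
              paste(x$spec$filters, collapse = "-"), x$spec$r,
              paste(c(x$spec$flatten, x$spec$fc, 2), collapse = " -> ")))
  if (!is.null(x$history)) {
    h <- x$history
    cat(sprintf("  epochs run: %d; best val loss %.4f at epoch %d\n",
                nrow(h), min(h$val_loss), which.min(h$val_loss)))
  }
  invisible(x)
}

#' @export
summary.atcnn <- function(object, ...) {
  print(object)
  print(object$spec)
  invisible(object)
}

#' Plot training history of an attention CNN
#'
#' @param x a trained `atcnn`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.atcnn <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = which.min(h$val_loss), lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
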