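#' Training configuration for the attention CNN
#'
#' Defaults follow the reference training protocol: 100 epochs maximum,
#' Adam with initial learning rate 0.001 decayed by a single (non-restarting)
#' cosine schedule, early stopping with patience 20 on the validation loss,
#' label smoothing 0.1, and minority-class oversampling of the training
#' split. Batch size (32) and the stratified 80/20 train/validation split are
#' this package's defaults (the protocol leaves them unstated).
#'
#' @param max_epochs maximum epochs (default 100).
#' @param lr0 initial learning rate (default 0.001).
#' @param patience early-stopping patience in epochs (default 20; must be
#'   less than `max_epochs`).
#' @param eps label-smoothing parameter (default 0.1).
#' @param symmetric symmetric label smoothing (default `FALSE`; see
#'   [smooth_labels()]).
#' @param batch_size mini-batch size (default 32).
#' @param val_fraction validation fraction when no validation set is given
#'   (default 0.2, stratified).
#' @param oversample balance the training split by oversampling the minority
#'   class (default `TRUE`).
#' @param seed seed governing initialization, splits, shuffling and dropout.
#' @param verbose print per-epoch progress (default `FALSE`).
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_epochs = 100, lr0 = 0.001, patience = 20,
                         eps = 0.1, symmetric = FALSE, batch_size = 32,
                         val_fraction = 0.2, oversample = TRUE, seed = 1,
                         verbose = FALSE) {
  if (lr0 < 0) stop("lr0 must be >= 0")
  if (patience >= max_epochs) stop("patience must be < max_epochs")
  if (eps < 0 || eps >= 1) stop("eps must be in [0, 1)")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  structure(list(max_epochs = as.integer(max_epochs), lr0 = lr0,
                 patience = as.integer(patience), eps = eps,
                 symmetric = symmetric, batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, oversample = oversample,
                 seed = as.integer(seed), verbose = verbose),
            class = "train_config")
}

#' Oversample the minority class to balance a training set
#'
#' Randomly duplicates minority-class samples (with replacement) until both
#' classes have the majority count. Only ever applied to the training split:
#' validation and test distributions are left untouched.
#'
#' @param images list of images or `H x W x N` array.
#' @param labels binary labels, one per image.
#' @param seed seed for the duplicate draw.
#' @return List with balanced `images` (same container type) and `labels`.
#' @export
oversample_minority <- function(images, labels, seed = 1) {
  is_arr <- !is.list(images)
  n <- if (is_arr) dim(images)[3] else length(images)
  stopifnot(n == length(labels))
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts == 0))
    stop("both classes must be present to oversample")
  if (counts[1] == counts[2]) return(list(images = images, labels = labels))
  minority <- as.integer(names(which.min(counts)))
  set.seed(seed)
  extra <- sample(which(labels == minority), max(counts) - min(counts),
                  replace = TRUE)
  idx <- c(seq_len(n), extra)
  images <- if (is_arr) images[, , idx, drop = FALSE] else images[idx]
  list(images = images, labels = labels[idx])
}

#' Cosine learning-rate decay
#'
#' Single non-restarting schedule `lr(t) = 0.5 lr0 (1 + cos(pi t / T))`:
#' starts at `lr0`, ends at 0, strictly decreasing.
#'
#' @param t epoch index, `0 <= t <= T`.
#' @param T total epochs.
#' @param lr0 initial learning rate.
#' @return The learning rate at epoch `t`.
#' @export
cosine_lr <- function(t, T, lr0) {
  if (any(t < 0) || any(t > T)) stop("t must lie in [0, T]")
  0.5 * lr0 * (1 + cos(pi * t / T))
}

# stratified index split: preserves class proportions within +-1
split_stratified <- function(labels, frac, seed) {
  set.seed(seed)
  val <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    val <- c(val, sample(idx, max(1, round(length(idx) * frac))))
  }
  list(train = setdiff(seq_along(labels), val), val = sort(val))
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)

adam_step <- function(params, grads, opt, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (nm in names(grads)) {
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * grads[[nm]]
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# mean loss + running-stat-free forward over batches (inference mode)
eval_loss <- function(model, x, y, eps, symmetric, batch_size = 64) {
  N <- dim(x)[3]
  probs <- numeric(N)
  for (s in seq(1, N, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, N)
    probs[idx] <- nn_forward(model, x[, , idx, drop = FALSE])$prob
  }
  list(loss = smoothed_bce(probs, smooth_labels(y, eps, symmetric)),
       acc = mean((probs >= 0.5) == (y == 1)))
}

#' Train an attention CNN on rendered EEG images
#'
#' Fits the classifier with Adam under a cosine learning-rate schedule and
#' the label-smoothed cross-entropy, oversampling the minority class of the
#' training split, and stopping early when the validation loss has not
#' improved (by more than 1e-5) for `patience` epochs. The returned model
#' carries the weights of the best validation epoch and a per-epoch history
#' (train/validation loss, validation accuracy, learning rate). Fully
#' deterministic given `config$seed`.
#'
#' @param images training images: list (as from [render_epochs()]) or
#'   `H x W x N` array, pixel values 0-255 or `[0, 1]`.
#' @param labels binary labels (1 = error trial), one per image.
#' @param val_images,val_labels optional held-out validation set; when
#'   omitted, a stratified `val_fraction` split of `images` is used.
#' @param spec an [atcnn_spec()] (default: canonical architecture).
#' @param config a [train_config()].
#' @param backend `"cpp"` (default) runs the fused single-precision training
#'   engine; `"R"` runs the double-precision reference implementation (slow;
#'   used for validation).
#' @return A trained `atcnn` object.
#' @export
train_atcnn <- function(images, labels, val_images = NULL, val_labels = NULL,
                        spec = atcnn_spec(), config = train_config(),
                        backend = c("cpp", "R")) {
  backend <- match.arg(backend)
  stopifnot(inherits(config, "train_config"))
  x <- if (is.list(images)) images_to_array(images) else images
  if (max(x) > 1) x <- x / 255
  labels <- as.integer(labels)
  if (is.null(val_images)) {
    sp <- split_stratified(labels, config$val_fraction, config$seed)
    xv <- x[, , sp$val, drop = FALSE]; yv <- labels[sp$val]
    x <- x[, , sp$train, drop = FALSE]; labels <- labels[sp$train]
  } else {
    xv <- if (is.list(val_images)) images_to_array(val_images) else val_images
    if (max(xv) > 1) xv <- xv / 255
    yv <- as.integer(val_labels)
  }
  if (dim(x)[3] == 0 || dim(xv)[3] == 0) stop("empty training or validation split")
  if (config$oversample && length(unique(labels)) == 2) {
    ov <- oversample_minority(x, labels, seed = config$seed)
    x <- ov$images; labels <- ov$labels
  }
  model <- atcnn(spec, seed = config$seed)
  n <- dim(x)[3]
  use_cpp <- backend == "cpp"
  if (use_cpp) {
    ptr <- cpp_trainer_create(model$params, unclass(spec),
                              max(config$batch_size, 64L))
  } else {
    opt <- adam_init(model$params)
  }
  set.seed(config$seed + 1L)
  best <- list(loss = Inf, params = model$params, state = model$state,
               epoch = 0L)
  hist <- data.frame()
  stale <- 0L
  momentum <- 0.1
  for (epoch in seq_len(config$max_epochs)) {
    lr <- cosine_lr(epoch - 1, config$max_epochs, config$lr0)
    ord <- sample.int(n)
    tr_loss <- 0; nb <- 0
    for (s in seq(1, n, by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1, n)]
      if (length(idx) < 2) next                    # BN needs >= 2
      ys <- smooth_labels(labels[idx], config$eps, config$symmetric)
      xb <- x[, , idx, drop = FALSE]
      if (use_cpp) {
        tr_loss <- tr_loss + cpp_trainer_step(ptr, xb, ys, lr)
        nb <- nb + 1
        next
      }
      fw <- nn_forward(model, xb, training = TRUE, keep_cache = TRUE)
      tr_loss <- tr_loss + smoothed_bce(fw$prob, ys)
      nb <- nb + 1
      grads <- nn_backward(model, fw$cache, ys)
      if (lr > 0) {       # frozen LR freezes the BN running statistics too
        for (m in seq_along(spec$filters)) {
          bs <- fw$cache$batch_stats[[m]]
          model$state[[paste0("rm", m)]] <-
            (1 - momentum) * model$state[[paste0("rm", m)]] + momentum * bs$mean
          model$state[[paste0("rv", m)]] <-
            (1 - momentum) * model$state[[paste0("rv", m)]] + momentum * bs$var
        }
        model$state$bn_t <- model$state$bn_t + 1L
      }
      upd <- adam_step(model$params, grads, opt, lr)
      model$params <- upd$params; opt <- upd$opt
    }
    if (use_cpp) {
      probs <- ptr_predict(ptr, xv, 64L)
      vl <- list(loss = smoothed_bce(probs, smooth_labels(yv, config$eps,
                                                          config$symmetric)),
                 acc = mean((probs >= 0.5) == (yv == 1)))
    } else {
      vl <- eval_loss(model, xv, yv, config$eps, config$symmetric)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = tr_loss / max(nb, 1),
                                   val_loss = vl$loss, val_acc = vl$acc))
    if (config$verbose)
      message(sprintf("epoch %3d  lr %.5f  train %.4f  val %.4f  acc %.3f",
                      epoch, lr, tr_loss / max(nb, 1), vl$loss, vl$acc))
    if (vl$loss < best$loss - 1e-5) {
      best <- list(loss = vl$loss, epoch = epoch)
      if (use_cpp) {
        snap <- cpp_trainer_get_params(ptr)
        best$params <- snap$params; best$state <- snap$state
      } else {
        best$params <- model$params; best$state <- model$state
      }
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  model$params <- best$params
  model$state <- best$state
  model$history <- hist
  model$best_epoch <- best$epoch
  model$trained <- TRUE
  model
}

# batched inference through a C++ trainer context
ptr_predict <- function(ptr, x, batch_size = 64L) {
  N <- dim(x)[3]
  probs <- numeric(N)
  for (s in seq(1, N, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, N)
    probs[idx] <- cpp_trainer_predict(ptr, x[, , idx, drop = FALSE])
  }
  probs
}
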