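#' Stratified k-fold partition
#'
#' Splits trial indices into `k` disjoint subsets of (as near as possible)
#' equal size, preserving the class proportions within one sample per fold.
#' `k = 1` returns a single subset holding every index.
#'
#' @param labels binary label vector.
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @return List of `k` integer index vectors (disjoint, union = all indices).
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1) {
  n <- length(labels)
  if (k > n) stop("k must not exceed the number of trials")
  if (k == 1) return(list(seq_len(n)))
  for (cl in unique(labels))
    if (sum(labels == cl) < k)
      stop("every class must have at least k members")
  set.seed(seed)
  folds <- vector("list", k)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    sizes <- vapply(folds, length, integer(1))
    ord <- order(sizes, seq_len(k))          # fill smallest folds first
    assign_to <- rep_len(ord, length(idx))   # round-robin: per-class +-1
    for (j in seq_along(idx))
      folds[[assign_to[j]]] <- c(folds[[assign_to[j]]], idx[j])
  }
  lapply(folds, sort)
}

#' Meta-dataset of per-channel predictions
#'
#' Stage-2 input for the stacking ensemble: an `N x n` matrix of hard binary
#' per-channel predictions (one column per channel, in a fixed order) plus
#' the true trial labels.
#'
#' @param P numeric `N x n` matrix with entries in `{0, 1}`.
#' @param y true binary labels, length `N`.
#' @param channel_order character vector of the `n` channel labels, in
#'   column order.
#' @return An object of class `meta_dataset`.
#' @export
meta_dataset <- function(P, y, channel_order) {
  P <- as.matrix(P)
  if (!all(P %in% c(0, 1))) stop("meta-features must be binary 0/1")
  if (nrow(P) != length(y)) stop("P rows must align with labels")
  if (ncol(P) != length(channel_order))
    stop("channel_order must name every column of P")
  colnames(P) <- channel_order
  structure(list(P = P, y = as.integer(y), channel_order = channel_order),
            class = "meta_dataset")
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat(sprintf("<meta_dataset> %d trials x %d channels (%s)\n", nrow(x$P),
              ncol(x$P), paste(x$channel_order, collapse = ", ")))
  invisible(x)
}

# default stage-1 learners: one attention CNN per channel
default_base_trainer <- function(images, labels, config, spec) {
  train_atcnn(images, labels, spec = spec, config = config)
}
default_base_predictor <- function(model, images) {
  predict(model, images, type = "class")
}

#' Build the out-of-fold meta-dataset
#'
#' Stage 1 of stacked generalization: the trials are split into `k`
#' stratified folds; for every fold and every channel in the group, a base
#' classifier is trained on the other `k - 1` folds and predicts the held-out
#' fold, so each trial's meta-feature row comes entirely from models that
#' never saw it. Rows keep the original trial order.
#'
#' @param ep a normalized `eeg_epochs` training set.
#' @param group channel group name (`"A"`-`"E"`, see [channel_group()]) or an
#'   explicit character vector of channels.
#' @param k number of folds (default 5).
#' @param spec an [atcnn_spec()] for the base models.
#' @param config a [train_config()] for the base models; the seed is offset
#'   per channel and fold.
#' @param base_trainer,base_predictor optional stand-ins for the base model
#'   (used by tests and by light-weight ensembles):
#'   `base_trainer(images, labels, config, spec)` must return a model,
#'   `base_predictor(model, images)` a vector of hard 0/1 labels.
#' @param size image side in pixels (default `spec$input_size`).
#' @return A `meta_dataset` with attribute `"folds"` (the fold index list).
#' @export
build_meta_dataset <- function(ep, group = "D", k = 5, spec = atcnn_spec(),
                               config = train_config(),
                               base_trainer = default_base_trainer,
                               base_predictor = default_base_predictor,
                               size = spec$input_size) {
  stopifnot(inherits(ep, "eeg_epochs"))
  channels <- if (length(group) == 1 && group %in% c("A", "B", "C", "D", "E"))
    channel_group(group) else toupper(group)
  missing_ch <- setdiff(channels, ep$channel_names)
  if (length(missing_ch))
    stop("channel(s) missing from the epoch set: ",
         paste(missing_ch, collapse = ", "))
  N <- n_trials(ep)
  folds <- stratified_kfold(ep$labels, k = k, seed = config$seed)
  P <- matrix(NA_real_, N, length(channels))
  for (ci in seq_along(channels)) {
    imgs <- render_epochs(ep, channels[ci], size = size)
    x <- images_to_array(imgs)
    for (fi in seq_along(folds)) {
      hold <- folds[[fi]]
      tr <- if (k == 1) hold else setdiff(seq_len(N), hold)
      cfg <- config
      cfg$seed <- config$seed + 100L * ci + fi
      model <- base_trainer(x[, , tr, drop = FALSE], ep$labels[tr], cfg, spec)
      P[hold, ci] <- base_predictor(model, x[, , hold, drop = FALSE])
    }
  }
  md <- meta_dataset(P, ep$labels, channels)
  attr(md, "folds") <- folds
  md
}

#' Train the stage-2 meta network
#'
#' A three-layer fully-connected network fuses the per-channel decisions:
#' `n` inputs (one per channel classifier), `ceil(n/2)` hidden ReLU units,
#' one sigmoid output thresholded at 0.5. Trained with full-batch Adam on the
#' binary cross-entropy. If the meta training labels contain a single class,
#' a constant majority predictor is returned with a warning.
#'
#' @param meta a [meta_dataset()].
#' @param hidden hidden-layer width (default `ceiling(n/2)`).
#' @param lr Adam learning rate (default 0.01).
#' @param epochs training epochs (default 200).
#' @param seed initialization seed.
#' @return An object of class `meta_mlp` (or `meta_constant` in the
#'   degenerate case), with a [predict][predict.meta_mlp] method.
#' @export
train_meta_network <- function(meta, hidden = NULL, lr = 0.01, epochs = 200,
                               seed = 1) {
  stopifnot(inherits(meta, "meta_dataset"))
  n <- ncol(meta$P)
  if (is.null(hidden)) hidden <- ceiling(n / 2)
  if (length(unique(meta$y)) < 2) {
    warning("meta labels contain a single class; returning a constant predictor")
    return(structure(list(value = meta$y[1],
                          channel_order = meta$channel_order),
                     class = "meta_constant"))
  }
  set.seed(seed)
  X <- t(meta$P); y <- meta$y                       # n x N
  W1 <- matrix(stats::rnorm(hidden * n, 0, sqrt(2 / n)), hidden, n)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(hidden, 0, sqrt(2 / hidden)), 1, hidden)
  b2 <- 0
  pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  opt <- adam_init(pars)
  N <- ncol(X)
  for (e in seq_len(epochs)) {
    Z1 <- pars$W1 %*% X + pars$b1
    A1 <- pmax(Z1, 0)
    p <- as.numeric(sigmoid(pars$W2 %*% A1 + pars$b2))
    dz2 <- matrix(p - y, 1) / N                     # BCE + sigmoid shortcut
    g <- list(W2 = dz2 %*% t(A1), b2 = sum(dz2))
    dA1 <- t(pars$W2) %*% dz2 * (Z1 > 0)
    g$W1 <- dA1 %*% t(X); g$b1 <- rowSums(dA1)
    upd <- adam_step(pars, g, opt, lr)
    pars <- upd$params; opt <- upd$opt
  }
  structure(list(pars = pars, hidden = hidden,
                 channel_order = meta$channel_order),
            class = "meta_mlp")
}

#' Predict from a trained meta network
#'
#' @param object a `meta_mlp`.
#' @param newdata binary `N x n` prediction matrix (columns in the training
#'   channel order) or a `meta_dataset`.
#' @param type `"class"` (default, threshold 0.5) or `"prob"`.
#' @param ... unused.
#' @return Vector of fused labels (or probabilities).
#' @export
predict.meta_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  P <- if (inherits(newdata, "meta_dataset")) newdata$P else as.matrix(newdata)
  if (ncol(P) != length(object$channel_order))
    stop("column count does not match the trained channel order")
  X <- t(P)
  A1 <- pmax(object$pars$W1 %*% X + object$pars$b1, 0)
  p <- as.numeric(sigmoid(object$pars$W2 %*% A1 + object$pars$b2))
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' @export
predict.meta_constant <- function(object, newdata, ...) {
  P <- if (inherits(newdata, "meta_dataset")) newdata$P else as.matrix(newdata)
  rep(as.integer(object$value), nrow(P))
}

#' Majority-vote fusion
#'
#' The baseline fusion rule: a trial is labelled 1 (error) iff strictly more
#' than half of the channel predictions are 1. With an even number of
#' channels a tie goes to the negative class ('more than half' read
#' strictly); the 9-channel group D cannot tie.
#'
#' @param P binary `N x n` matrix of per-channel predictions.
#' @return Integer vector of `N` fused labels.
#' @export
majority_vote <- function(P) {
  P <- as.matrix(P)
  if (!all(P %in% c(0, 1))) stop("predictions must be binary 0/1")
  as.integer(rowSums(P) > ncol(P) / 2)
}

#' Fit the full two-stage stacking ensemble
#'
#' Runs stacked generalization end to end: builds the out-of-fold
#' meta-dataset with one base classifier per channel per fold, trains the
#' stage-2 meta network on it, then retrains one final base model per channel
#' on the complete training set (the models used at prediction time; fold
#' models are discarded after producing their out-of-fold predictions).
#'
#' @inheritParams build_meta_dataset
#' @param meta_seed seed for the meta-network initialization.
#' @return An object of class `errp_ensemble` holding the final base models,
#'   the meta network, the meta-dataset and the channel order.
#' @export
errp_ensemble <- function(ep, group = "D", k = 5, spec = atcnn_spec(),
                          config = train_config(),
                          base_trainer = default_base_trainer,
                          base_predictor = default_base_predictor,
                          size = spec$input_size, meta_seed = 1) {
  channels <- if (length(group) == 1 && group %in% c("A", "B", "C", "D", "E"))
    channel_group(group) else toupper(group)
  md <- build_meta_dataset(ep, channels, k = k, spec = spec, config = config,
                           base_trainer = base_trainer,
                           base_predictor = base_predictor, size = size)
  meta <- train_meta_network(md, seed = meta_seed)
  base_models <- vector("list", length(channels))
  names(base_models) <- channels
  for (ci in seq_along(channels)) {
    imgs <- render_epochs(ep, channels[ci], size = size)
    x <- images_to_array(imgs)
    cfg <- config
    cfg$seed <- config$seed + 100L * ci
    base_models[[ci]] <- base_trainer(x, ep$labels, cfg, spec)
  }
  structure(list(base_models = base_models, meta = meta, meta_data = md,
                 channel_order = channels, base_predictor = base_predictor,
                 size = size),
            class = "errp_ensemble")
}

#' Predict with the stacking ensemble
#'
#' Per trial: every channel's final base model casts a hard vote; the meta
#' network fuses the votes into the final label.
#'
#' @param object an `errp_ensemble`.
#' @param newdata a normalized `eeg_epochs` object containing every channel
#'   of the ensemble.
#' @param ... unused.
#' @return Integer vector of predicted labels, with the per-channel
#'   prediction matrix attached as attribute `"P"`.
#' @export
predict.errp_ensemble <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "eeg_epochs"))
  missing_ch <- setdiff(object$channel_order, newdata$channel_names)
  if (length(missing_ch))
    stop("channel(s) missing from the epoch set: ",
         paste(missing_ch, collapse = ", "))
  P <- matrix(0, n_trials(newdata), length(object$channel_order))
  for (ci in seq_along(object$channel_order)) {
    imgs <- render_epochs(newdata, object$channel_order[ci],
                          size = object$size)
    P[, ci] <- object$base_predictor(object$base_models[[ci]],
                                     images_to_array(imgs))
  }
  out <- predict(object$meta, P)
  attr(out, "P") <- P
  out
}

#' @export
print.errp_ensemble <- function(x, ...) {
  cat(sprintf("<errp_ensemble> %d channels (%s), meta %s\n",
              length(x$channel_order),
              paste(x$channel_order, collapse = ", "),
              if (inherits(x$meta, "meta_mlp"))
                sprintf("%d -> %d -> 1", length(x$channel_order),
                        x$meta$hidden)
              else "constant"))
  invisible(x)
}

#' Fuse per-channel predictions for new epochs
#'
#' Functional form of [predict.errp_ensemble()]: applies the final base
#' models and the trained meta network to a new epoch set.
#'
#' @param base_models named list of per-channel models (names = channels).
#' @param meta trained meta model whose `channel_order` matches
#'   `names(base_models)`.
#' @param ep a normalized `eeg_epochs`.
#' @param base_predictor see [build_meta_dataset()].
#' @param size image side in pixels.
#' @return Integer vector of fused labels (attribute `"P"` holds the votes).
#' @export
ensemble_predict <- function(base_models, meta, ep,
                             base_predictor = default_base_predictor,
                             size = 224) {
  if (!identical(names(base_models), meta$channel_order))
    stop("base model names do not match the meta network channel order")
  obj <- structure(list(base_models = base_models, meta = meta,
                        channel_order = meta$channel_order,
                        base_predictor = base_predictor, size = size),
                   class = "errp_ensemble")
  predict(obj, ep)
}
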