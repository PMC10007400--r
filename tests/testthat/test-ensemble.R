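# Stacked generalization: folds, meta-dataset, meta network, fusion.

test_that("stratified k-fold partitions indices evenly and by class", {
  set.seed(31)
  y <- rep(c(0, 1), c(80, 20))
  folds <- stratified_kfold(y, k = 5, seed = 2)
  expect_length(folds, 5)
  sizes <- vapply(folds, length, integer(1))
  expect_equal(sizes, rep(20L, 5))               # n = 100, k = 5
  # disjoint and complete (set-algebra oracle)
  all_idx <- sort(unlist(folds))
  expect_identical(all_idx, seq_along(y))
  # class proportions within one sample per fold
  pos <- vapply(folds, function(f) sum(y[f] == 1), integer(1))
  expect_true(all(abs(pos - 4) <= 1))
  # k = 1 returns everything in one subset
  expect_identical(stratified_kfold(y, k = 1), list(seq_along(y)))
  expect_error(stratified_kfold(y, k = 200), "exceed")
  expect_error(stratified_kfold(rep(c(0, 1), c(98, 2)), k = 5), "k members")
})

test_that("meta dataset validates binary entries and alignment", {
  P <- matrix(c(1, 0, 1, 0), 2, 2)
  md <- meta_dataset(P, c(1, 0), c("FCZ", "CZ"))
  expect_s3_class(md, "meta_dataset")
  expect_error(meta_dataset(P * 0.5, c(1, 0), c("FCZ", "CZ")), "binary")
  expect_error(meta_dataset(P, c(1, 0, 1), c("FCZ", "CZ")), "align")
})

test_that("out-of-fold meta features come from models that never saw the trial", {
  ep <- decodable_epochs(40, channels = c("FCZ", "CZ"), seed = 3)
  # leakage audit: the base trainer records which trial indices it saw (the
  # image row count at column 1 encodes nothing, so audit via fold indices
  # threaded through a closure over the call sequence)
  seen_by_fold <- list()
  audit_trainer <- function(images, labels, config, spec) {
    seen_by_fold[[length(seen_by_fold) + 1]] <<- dim(images)[3]
    oracle_trainer(images, labels, config, spec)
  }
  md <- build_meta_dataset(ep, c("FCZ", "CZ"), k = 4,
                           config = train_config(seed = 2),
                           base_trainer = audit_trainer,
                           base_predictor = oracle_predictor, size = 64)
  folds <- attr(md, "folds")
  expect_identical(sort(unlist(folds)), 1:40)
  expect_true(all(!is.na(md$P)))
  # each fold model trained on exactly the other k - 1 folds
  expect_length(seen_by_fold, 8)                 # 2 channels x 4 folds
  expect_equal(unlist(seen_by_fold),
               rep(40 - vapply(folds, length, integer(1)), 2))
  # with an oracle base, every column reproduces the labels exactly
  expect_true(all(md$P[, 1] == md$y))
  expect_true(all(md$P[, 2] == md$y))
  expect_equal(dim(md$P), c(40, 2))
  expect_error(build_meta_dataset(ep, "D", k = 2), "missing")
})

test_that("the meta network has the published geometry and learns a copy task", {
  set.seed(33)
  n <- 9
  P <- matrix(rbinom(9 * 200, 1, 0.5), 200, n)
  y <- P[, 1]
  md <- meta_dataset(P, y, paste0("CH", 1:n))
  mm <- train_meta_network(md, seed = 1)
  expect_equal(mm$hidden, 5)                     # ceil(9 / 2)
  expect_equal(mean(predict(mm, md) == y), 1)    # copy task learned exactly
  # degenerate labels fall back to a constant predictor with a warning
  md1 <- meta_dataset(P, rep(1, 200), paste0("CH", 1:n))
  expect_warning(mc <- train_meta_network(md1), "single class")
  expect_true(all(predict(mc, P) == 1))
})

test_that("stacking beats majority voting when the fusion rule is an XOR", {
  accs <- vapply(1:5, function(s) {
    set.seed(s)
    N <- 2000
    y <- rbinom(N, 1, 0.5)
    a <- rbinom(N, 1, 0.5)
    b <- xor(y, a) * 1
    flip <- function(v) ifelse(runif(N) < 0.05, 1 - v, v)
    P <- cbind(flip(a), flip(b),
               matrix(rbinom(7 * N, 1, 0.3), N, 7))
    tr <- 1:1000; te <- 1001:2000
    mm <- train_meta_network(meta_dataset(P[tr, ], y[tr], paste0("C", 1:9)),
                             seed = s)
    c(meta = mean(predict(mm, P[te, ]) == y[te]),
      mv = mean(majority_vote(P[te, ]) == y[te]))
  }, numeric(2))
  expect_gt(stats::median(accs["meta", ] - accs["mv", ]), 0.10)
})

test_that("majority vote equals the exhaustive counting oracle", {
  expect_identical(majority_vote(matrix(c(1, 1, 0), 1)), 1L)
  expect_identical(majority_vote(matrix(c(1, 0), 1)), 0L)   # tie -> negative
  # all 2^9 nine-channel vote patterns
  grid <- as.matrix(expand.grid(rep(list(0:1), 9)))
  oracle <- apply(grid, 1, function(r) as.integer(sum(r == 1) > sum(r == 0)))
  expect_identical(majority_vote(grid), unname(oracle))
  expect_error(majority_vote(matrix(0.5, 2, 3)), "binary")
})

test_that("ensemble prediction composes base votes through the meta model", {
  ep <- decodable_epochs(30, channels = c("FCZ", "CZ", "FZ"), seed = 4)
  ens <- errp_ensemble(ep, c("FCZ", "CZ", "FZ"), k = 3,
                       config = train_config(seed = 1),
                       base_trainer = oracle_trainer,
                       base_predictor = oracle_predictor, size = 64)
  te <- decodable_epochs(20, channels = c("FCZ", "CZ", "FZ"), seed = 9)
  pred <- predict(ens, te)
  expect_identical(as.integer(pred), te$labels)  # oracle bases are perfect
  expect_equal(dim(attr(pred, "P")), c(20, 3))
  expect_output(print(ens), "3 channels")

  # meta replaced by an identity-on-FCZ network passes FCz votes through
  id_meta <- structure(list(
    pars = list(W1 = matrix(c(1, 0, 0), 1, 3), b1 = 0,
                W2 = matrix(1, 1, 1), b2 = -0.5),
    hidden = 1, channel_order = c("FCZ", "CZ", "FZ")), class = "meta_mlp")
  pred2 <- ensemble_predict(ens$base_models, id_meta, te,
                            base_predictor = oracle_predictor, size = 64)
  expect_identical(as.integer(pred2), as.integer(attr(pred2, "P")[, 1]))

  # degenerate bases: everything 0 means no detections at all
  zero_pred <- function(model, images) rep(0L, dim(images)[3])
  pred3 <- ensemble_predict(ens$base_models, ens$meta, te,
                            base_predictor = zero_pred, size = 64)
  cm <- compute_metrics(confusion_counts(as.integer(pred3), te$labels))
  expect_true(all(pred3 == 0))
  expect_equal(cm$sensitivity, 0)
})
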