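# Training protocol: oversampling, schedule, early stopping, determinism.

test_that("minority oversampling balances the class counts", {
  set.seed(21)
  x <- array(runif(8 * 8 * 100), c(8, 8, 100))
  y <- rep(c(0, 1), c(80, 20))
  ov <- oversample_minority(x, y, seed = 1)
  # counting oracle on the output histogram
  counts <- c(sum(ov$labels == 0), sum(ov$labels == 1))
  expect_equal(counts, c(80, 80))
  expect_equal(dim(ov$images)[3], 160)
  # duplicates really are copies of minority images
  extra <- 101:160
  expect_true(all(ov$labels[extra] == 1))
  # balanced input is returned unchanged
  yb <- rep(c(0, 1), 50)
  expect_identical(oversample_minority(x, yb)$labels, yb)
  expect_error(oversample_minority(x, rep(0, 100)), "both classes")
})

test_that("cosine decay interpolates lr0 -> 0 and rejects t > T", {
  expect_equal(cosine_lr(0, 100, 0.001), 0.001)
  expect_equal(cosine_lr(100, 100, 0.001), 0, tolerance = 1e-18)
  expect_equal(cosine_lr(50, 100, 0.001), 0.0005)
  lr <- cosine_lr(0:100, 100, 0.001)
  expect_true(all(diff(lr) < 0))                 # strictly decreasing
  expect_error(cosine_lr(101, 100, 0.001), "\\[0, T\\]")
})

test_that("early stopping obeys the patience contract", {
  # frozen learning rate (lr0 = 0): the validation loss can never improve
  # after epoch 1, so patience = 1 stops the run at epoch 2
  d <- tiny_images(24, seed = 6)
  cfg <- train_config(max_epochs = 10, patience = 1, lr0 = 0,
                      batch_size = 8, seed = 2)
  m <- train_atcnn(d$x, d$y, spec = tiny_spec(), config = cfg)
  expect_equal(nrow(m$history), 2)
  expect_equal(m$best_epoch, 1)
})

test_that("training is deterministic given the seed and restores best weights", {
  d <- tiny_images(40, seed = 7)
  cfg <- train_config(max_epochs = 3, patience = 2, batch_size = 8, seed = 11)
  m1 <- train_atcnn(d$x, d$y, spec = tiny_spec(), config = cfg)
  m2 <- train_atcnn(d$x, d$y, spec = tiny_spec(), config = cfg)
  expect_identical(tail(m1$history$val_loss, 1), tail(m2$history$val_loss, 1))
  expect_identical(m1$params$fW3, m2$params$fW3)
  # returned weights belong to the epoch with the smallest validation loss
  expect_equal(m1$best_epoch, which.min(m1$history$val_loss))
})

test_that("the tiny network recovers separable labels end to end", {
  d <- tiny_images(120, seed = 8)
  te <- tiny_images(60, seed = 9)
  cfg <- train_config(max_epochs = 8, patience = 3, batch_size = 16, seed = 3)
  m <- train_atcnn(d$x, d$y, spec = tiny_spec(), config = cfg)
  acc <- mean(predict(m, te$x) == te$y)
  expect_gt(acc, 0.8)
  # both engines classify the same way
  accR <- mean(predict(m, te$x, backend = "R") == te$y)
  expect_equal(acc, accR, tolerance = 0.05)
  expect_output(print(m), "trained")
})

test_that("with permuted labels validation accuracy stays near chance", {
  d <- tiny_images(80, seed = 10)
  set.seed(12)
  y_perm <- sample(d$y)
  cfg <- train_config(max_epochs = 3, patience = 2, batch_size = 16, seed = 5)
  m <- train_atcnn(d$x, y_perm, spec = tiny_spec(), config = cfg)
  n_val <- round(0.2 * 80)
  acc <- tail(m$history$val_acc, 1)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n_val) + 0.05)
})

test_that("train_config validates its inputs", {
  expect_error(train_config(patience = 100, max_epochs = 100), "patience")
  expect_error(train_config(eps = 1), "eps")
  expect_error(train_config(val_fraction = 1), "val_fraction")
})
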