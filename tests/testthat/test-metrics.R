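# Performance metrics and the desk-scale experiment runner.

test_that("confusion counts match a counting-loop oracle", {
  cc <- confusion_counts(c(1, 0), c(1, 0))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 1L, TN = 1L, FP = 0L, FN = 0L), ignore_attr = TRUE)
  cc2 <- confusion_counts(rep(0, 10), rep(c(1, 0), 5))
  expect_equal(cc2$FN, 5)
  expect_equal(cc2$TP, 0)
  set.seed(41)
  pred <- rbinom(200, 1, 0.4); truth <- rbinom(200, 1, 0.3)
  cc3 <- confusion_counts(pred, truth)
  tp <- fn <- tn <- fp <- 0
  for (i in 1:200) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
  }
  expect_equal(list(cc3$TP, cc3$FN, cc3$TN, cc3$FP), list(tp, fn, tn, fp))
  expect_equal(cc3$TP + cc3$FN + cc3$TN + cc3$FP, 200)
  expect_error(confusion_counts(1, c(1, 0)), "length")
  expect_error(confusion_counts(c(2, 0), c(1, 0)), "binary")
})

test_that("metrics match direct formula evaluation on all tables with n <= 6", {
  expect_equal(compute_metrics(confusion_counts(c(1, 0), c(1, 0))),
               list(accuracy = 1, sensitivity = 1, specificity = 1))
  m <- compute_metrics(confusion_counts(rep(0, 10), rep(c(1, 0), 5)))
  expect_equal(m, list(accuracy = 0.5, sensitivity = 0, specificity = 1))
  # exhaustive enumeration of every confusion table with n <= 6
  for (n in 1:6) {
    parts <- expand.grid(TP = 0:n, FN = 0:n, TN = 0:n, FP = 0:n)
    parts <- parts[rowSums(parts) == n, ]
    for (i in seq_len(nrow(parts))) {
      p <- parts[i, ]
      cc <- structure(as.list(p), class = "confusion_counts")
      got <- suppressWarnings(compute_metrics(cc))
      expect_equal(got$accuracy, (p$TP + p$TN) / n)
      expect_equal(got$sensitivity,
                   if (p$TP + p$FN == 0) NA_real_ else p$TP / (p$TP + p$FN))
      expect_equal(got$specificity,
                   if (p$TN + p$FP == 0) NA_real_ else p$TN / (p$TN + p$FP))
    }
  }
  # undefined ratios warn and yield NA, never silent zeros
  expect_warning(z <- compute_metrics(confusion_counts(c(0, 0), c(0, 0))),
                 "sensitivity undefined")
  expect_true(is.na(z$sensitivity))
})

test_that("the experiment runner aggregates repeats and keeps one vote matrix", {
  ec <- experiment_config(n_train = 40, n_test = 40, error_rate = 0.3,
                          group = c("FCZ", "CZ", "FZ"), k = 2, repeats = 2,
                          seed = 7, base_trainer = oracle_trainer,
                          base_predictor = oracle_predictor)
  # oracle bases don't need real signals; swap the simulator-driven epochs
  # for decodable ones is not possible here, so run with real simulation and
  # oracle predictors that read the rendered trace shape (meaningless labels
  # but valid plumbing): check structure + audit only.
  res <- run_group_experiment(ec)
  expect_s3_class(res, "errp_experiment")
  expect_equal(res$method, c("FCZ", "CZ", "FZ", "majority_vote", "stacking"))
  expect_true(all(c("accuracy", "accuracy_sd", "sensitivity",
                    "specificity") %in% names(res)))
  reps <- attr(res, "repeats")
  expect_length(reps, 2)
  # majority voting and stacking consumed the SAME per-channel vote matrix
  for (r in reps) {
    expect_identical(r$majority_pred, majority_vote(r$P))
    expect_length(r$stacking_pred, nrow(r$P))
  }
  # single repeat: SD reported as 0
  ec1 <- ec; ec1$repeats <- 1L
  res1 <- run_group_experiment(ec1)
  expect_true(all(res1$accuracy_sd == 0))
  expect_output(print(res1), "1 repeat")
})

test_that("the paired method comparison reads per-repeat accuracies", {
  fake_rep <- function(a_stack, a_mv) {
    list(metrics = list(stacking = list(accuracy = a_stack),
                        majority_vote = list(accuracy = a_mv)))
  }
  fake <- structure(data.frame(method = "stacking"),
                    class = c("errp_experiment", "data.frame"),
                    repeats = list(fake_rep(0.9, 0.8), fake_rep(0.85, 0.82),
                                   fake_rep(0.88, 0.79)))
  tt <- compare_methods(fake)
  expect_s3_class(tt, "htest")
  expect_gt(tt$estimate, 0)
})
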