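# Preprocessing chain: CAR, Butterworth band-pass, ICA, epoching,
# normalization.

mk_rec <- function(data, rate = 512, channels = NULL,
                   events = data.frame(sample = integer(0),
                                       label = character(0))) {
  if (is.null(channels)) channels <- paste0("C", seq_len(nrow(data)))
  eeg_recording(data, rate, channels, events)
}

test_that("common average reference removes the cross-channel mean", {
  # common mode is removed entirely
  rec <- mk_rec(matrix(5, 3, 100))
  expect_true(all(apply_car(rec)$data == 0))
  # an already zero-mean pair is untouched
  rec2 <- mk_rec(rbind(rep(1, 50), rep(-1, 50)))
  expect_identical(apply_car(rec2)$data, rec2$data)
  # random input equals the brute-force column-loop subtraction
  set.seed(1)
  x <- matrix(rnorm(400), 4, 100)
  out <- apply_car(mk_rec(x))$data
  ref <- x
  for (j in seq_len(ncol(x))) ref[, j] <- x[, j] - mean(x[, j])
  expect_equal(out, ref, ignore_attr = TRUE, tolerance = 1e-12)
  # per-sample mean of the output is 0 and the operation is idempotent
  expect_lt(max(abs(colMeans(out))), 1e-9)
  expect_equal(apply_car(apply_car(rec2))$data, apply_car(rec2)$data,
               tolerance = 1e-9)
  expect_error(apply_car(mk_rec(matrix(1, 1, 10))), "2 channels")
})

test_that("band-pass filter kills DC, passes mid-band, attenuates 50 Hz", {
  rate <- 512
  t <- (0:(4 * rate - 1)) / rate
  mid <- (rate + 1):(3 * rate)                 # away from edges
  rec <- mk_rec(rbind(rep(1, length(t)),       # DC
                      sin(2 * pi * 5 * t),     # mid-band
                      sin(2 * pi * 50 * t)))   # line-noise band
  f <- bandpass_filter(rec, 1, 10, order = 3)
  expect_lt(max(abs(f$data[1, mid])), 1e-6)
  expect_lt(abs(max(abs(f$data[2, mid])) - 1), 0.05)
  expect_lt(max(abs(f$data[3, mid])), 10^(-20 / 20))  # >= 20 dB down
  # length preserved; invalid bands rejected
  expect_equal(ncol(f$data), length(t))
  expect_error(bandpass_filter(rec, 0, 10), "band edges")
  expect_error(bandpass_filter(rec, 10, 300), "band edges")
})

test_that("epoch extraction matches the stated window arithmetic", {
  rate <- 512
  cfg <- sim_config(n_trials = 6, error_rate = 0.5, channels = c("FCZ", "CZ"),
                    rate = rate, seed = 2)
  rec <- simulate_recording(cfg)
  ep <- extract_epochs(rec, window = c(-0.2, 0.8))
  expect_equal(dim(ep$data)[3], 512)           # 1 s at 512 Hz
  expect_equal(n_trials(ep), 6)
  # an event at sample 0 cannot honour the pre-stimulus window
  rec$events <- rbind(rec$events, data.frame(sample = 0, label = "error"))
  expect_warning(ep2 <- extract_epochs(rec), "dropped")
  expect_equal(n_trials(ep2), 6)
  expect_equal(attr(ep2, "dropped"), 1)
  # label multiset of retained events is preserved, in order
  expect_identical(ep2$labels, as.integer(rec$events$label[1:6] == "error"))
})

test_that("min-max normalization maps each trace to [0, 1]", {
  data <- array(0, c(2, 1, 3))
  data[1, 1, ] <- c(0, 5, 10)
  data[2, 1, ] <- c(7, 7, 7)
  ep <- eeg_epochs(data, c(0, 1), rate = 3, window = c(-0.2, 0.8),
                   channel_names = "FCZ")
  expect_warning(out <- normalize_epochs(ep), "constant")
  expect_equal(out$data[1, 1, ], c(0, 0.5, 1))
  expect_equal(out$data[2, 1, ], rep(0.5, 3))  # declared convention
  # random traces end up with exact min 0 / max 1; idempotent
  set.seed(3)
  cfg <- sim_config(n_trials = 5, error_rate = 0.5, channels = c("FCZ", "CZ"),
                    seed = 3)
  nrm <- normalize_epochs(simulate_epochs(cfg))
  for (i in 1:5) for (ch in 1:2) {
    expect_identical(min(nrm$data[i, ch, ]), 0)
    expect_identical(max(nrm$data[i, ch, ]), 1)
  }
  expect_equal(normalize_epochs(nrm)$data, nrm$data, tolerance = 1e-12)
})

test_that("ICA artifact removal reduces frontal blink power, keeps the ErrP", {
  # 40 trials x 1.5 s at 128 Hz = 60 s, 6 channels: enough for FastICA
  chs <- c("FZ", "F1", "F2", "FCZ", "CZ", "PZ")
  mk <- function(artifact_rate) {
    cfg <- sim_config(n_trials = 40, error_rate = 0.3, channels = chs,
                      rate = 128, noise_sd = 2, artifact_rate = artifact_rate,
                      seed = 21)
    bandpass_filter(apply_car(simulate_recording(cfg, inter_trial = 1.5)),
                    1, 10)
  }
  lowfreq_power <- function(rec) {
    lp <- bandpass_filter(rec, 0.5, 2, order = 2)
    mean(lp$data[rec$channel_names == "FZ", ]^2)
  }
  noisy <- mk(artifact_rate = 0.8)
  clean <- remove_artifacts(noisy, "ica", seed = 4)
  expect_gte(attr(clean, "rejected"), 1)
  expect_lt(lowfreq_power(clean), lowfreq_power(noisy))
  # no artifacts: the difference wave at FCz survives ICA (r >= 0.9)
  quiet <- mk(artifact_rate = 0)
  quiet_ica <- remove_artifacts(quiet, "ica", seed = 4)
  dw <- function(rec) {
    ep <- extract_epochs(rec)
    colMeans(ep$data[ep$labels == 1, "FCZ", ]) -
      colMeans(ep$data[ep$labels == 0, "FCZ", ])
  }
  expect_gte(cor(dw(quiet), dw(quiet_ica)), 0.9)
  # identity and error modes
  expect_identical(remove_artifacts(noisy, "none"), noisy)
  short <- mk_rec(matrix(rnorm(4 * 100), 4, 100))
  expect_error(remove_artifacts(short, "ica"), "30 s")
  few <- mk_rec(matrix(rnorm(2 * 20000), 2, 20000))
  expect_error(remove_artifacts(few, "ica"), "4 channels")
})

test_that("preprocess() runs CAR -> band-pass -> epoch -> normalize in order", {
  cfg <- sim_config(n_trials = 8, error_rate = 0.5, channels = c("FCZ", "CZ"),
                    seed = 6)
  ep <- preprocess(simulate_recording(cfg))
  expect_true(ep$normalized)
  expect_equal(n_trials(ep), 8)
  meta <- attr(ep, "preprocess")
  expect_true(meta$car)
  expect_equal(meta$band, c(1, 10))
  expect_false(meta$ica)
})
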