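# Synthetic ErrP generator: template shape, scalp topography, epoch and
# recording simulation.

test_that("template is a triphasic complex with extrema at the stated latencies", {
  p <- errp_template_params()
  w <- errp_template(p, duration = 0.8)
  rate <- p$rate
  # global minimum at the large negative deflection, ~250 ms
  expect_equal(which.min(w) - 1, round(0.250 * rate), tolerance = 0,
               ignore_attr = TRUE)
  # brute-force scan for interior local extrema of the discrete waveform
  n <- length(w)
  interior <- 2:(n - 1)
  is_max <- interior[w[interior] > w[interior - 1] & w[interior] > w[interior + 1]]
  is_min <- interior[w[interior] < w[interior - 1] & w[interior] < w[interior + 1]]
  # keep only extrema with non-negligible amplitude (tails are flat zero)
  is_max <- is_max[abs(w[is_max]) > 0.1]
  is_min <- is_min[abs(w[is_min]) > 0.1]
  expect_length(is_max, 2)
  expect_length(is_min, 1)
  found <- sort(c(is_max, is_min)) - 1          # 0-based sample indices
  expect_true(all(abs(found - round(p$peak_latencies * rate)) <= 1))
})

test_that("template edge cases: zero amplitudes, support, invalid params", {
  p0 <- errp_template_params(peak_amplitudes = c(0, 0, 0))
  expect_true(all(errp_template(p0, 0.8) == 0))
  # zero outside bump support (numerical tolerance)
  p <- errp_template_params()
  w <- errp_template(p, 0.8)
  early <- w[1:round(0.05 * p$rate)]            # 150 ms before first peak at 3 sd
  expect_lt(max(abs(early)), 1e-3 * max(abs(w)))
  expect_error(errp_template(p, 0.3), "latency")
  expect_error(errp_template_params(peak_latencies = c(0.3, 0.25, 0.32)),
               "increasing")
  expect_error(errp_template_params(peak_widths = c(0, 0.01, 0.01)), "width")
})

test_that("scalp gain anchors at FCz and decays away from it", {
  topo <- default_topography(c("FCZ", "CZ", "FZ", "C1", "F1", "OZ", "PZ"))
  expect_identical(scalp_gain("FCZ", topo), 1)
  expect_identical(scalp_gain("OZ", topo), 0)   # outside support
  # exhaustive comparison: nothing exceeds the FCz anchor
  for (ch in names(topo)) expect_lte(scalp_gain(ch, topo), 1)
  # nearest ring stronger than the next ring out
  expect_gt(scalp_gain("CZ", topo), scalp_gain("PZ", topo))
  expect_error(scalp_gain("XX9", default_topography("FCZ")), "unknown")
  expect_error(scalp_gain("FZ", topo[c("FCZ", "CZ")]), "not present")
})

test_that("simulated labels follow the configured error rate", {
  cfg <- sim_config(n_trials = 1000, error_rate = 0.2, channels = "FCZ",
                    seed = 7)
  ep <- simulate_epochs(cfg)
  expect_lt(abs(mean(ep$labels) - 0.2), 3 * sqrt(0.2 * 0.8 / 1000))
  # degenerate rate
  ep0 <- simulate_epochs(sim_config(n_trials = 50, error_rate = 0,
                                    channels = "FCZ", seed = 1))
  expect_true(all(ep0$labels == 0))
})

test_that("label marginal converges at n = 10000 within 3 binomial SDs", {
  cfg <- sim_config(n_trials = 10000, error_rate = 0.3, channels = "FCZ",
                    noise_sd = 0, seed = 12)
  ep <- simulate_epochs(cfg)
  expect_lt(abs(mean(ep$labels) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("grand-average difference wave has its trough at 200-300 ms", {
  cfg <- sim_config(n_trials = 300, error_rate = 0.3, channels = "FCZ",
                    seed = 3)
  ep <- simulate_epochs(cfg)
  diff_wave <- colMeans(ep$data[ep$labels == 1, 1, ]) -
    colMeans(ep$data[ep$labels == 0, 1, ])
  t_min <- (which.min(diff_wave) - 1) / cfg$rate + ep$window[1]
  expect_gte(t_min, 0.20)
  expect_lte(t_min, 0.30)
})

test_that("simulation is deterministic and SNR scales with template amplitude", {
  cfg <- sim_config(n_trials = 30, error_rate = 0.3, channels = c("FCZ", "CZ"),
                    seed = 42)
  expect_identical(simulate_epochs(cfg)$data, simulate_epochs(cfg)$data)
  peak <- function(scale) {
    tpl <- errp_template_params(peak_amplitudes = scale * c(3, -6, 4))
    ep <- simulate_epochs(cfg, tpl)
    d <- colMeans(ep$data[ep$labels == 1, 1, ]) -
      colMeans(ep$data[ep$labels == 0, 1, ])
    max(abs(d))
  }
  peaks <- vapply(c(0.5, 1, 2), peak, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("recordings carry the right events and round-trip through epoching", {
  cfg <- sim_config(n_trials = 10, error_rate = 0.3, channels = c("FCZ", "CZ"),
                    seed = 5)
  rec <- simulate_recording(cfg, inter_trial = 1.5)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(nrow(rec$events), 10)
  ep <- extract_epochs(rec)
  expect_equal(n_trials(ep), 10)
  expect_identical(ep$labels, as.integer(rec$events$label == "error"))
  # same label stream as the epoch simulator under the same seed
  expect_identical(ep$labels, simulate_epochs(cfg)$labels)
  expect_error(simulate_recording(cfg, inter_trial = 0.5), "inter_trial")
})

test_that("artifact injection is off at rate 0 and visible at rate 1", {
  base <- sim_config(n_trials = 8, error_rate = 0, channels = c("FZ", "CZ"),
                     noise_sd = 1, seed = 9)
  quiet <- simulate_epochs(base)
  noisy_cfg <- base; noisy_cfg$artifact_rate <- 1
  noisy <- simulate_epochs(noisy_cfg)
  # blinks are frontal: FZ range inflates, CZ untouched
  expect_gt(max(abs(noisy$data[, "FZ", ])), 5 * max(abs(quiet$data[, "FZ", ])))
  expect_identical(noisy$data[, "CZ", ], quiet$data[, "CZ", ])
})
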