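#' ErrP template parameters
#'
#' The error-related potential is modelled as a triphasic complex: a small
#' positive peak near 200 ms after feedback, a large negative peak near
#' 250 ms and a second positive peak near 320 ms. Each phase is a signed
#' Gaussian bump; the template is their sum.
#'
#' @param peak_latencies peak centres in seconds after feedback onset,
#'   strictly increasing, all in (0, 0.8).
#' @param peak_amplitudes signed peak amplitudes in microvolts. The default
#'   makes the middle (negative) deflection the largest, as observed at FCz.
#'   No quantitative amplitudes are published for this waveform; these
#'   defaults are free parameters chosen to look like a typical feedback ERP.
#' @param peak_widths Gaussian standard deviations in seconds, all > 0. The
#'   defaults are narrow enough that the composite waveform's extrema stay on
#'   the nominal latencies despite bump overlap.
#' @param rate sampling rate in Hz.
#' @return An object of class `errp_template_params`.
#' @export
#' @examples
#' p <- errp_template_params()
#' w <- errp_template(p, duration = 0.8)
errp_template_params <- function(peak_latencies = c(0.200, 0.250, 0.320),
                                 peak_amplitudes = c(3, -6, 4),
                                 peak_widths = c(0.015, 0.018, 0.020),
                                 rate = 512) {
  if (length(peak_latencies) != length(peak_amplitudes) ||
      length(peak_latencies) != length(peak_widths))
    stop("latencies, amplitudes and widths must have equal length")
  if (any(diff(peak_latencies) <= 0))
    stop("peak latencies must be strictly increasing")
  if (any(peak_latencies <= 0) || any(peak_latencies >= 0.8))
    stop("peak latencies must lie in (0, 0.8) seconds")
  if (any(peak_widths <= 0)) stop("peak widths must be > 0")
  if (rate <= 0) stop("rate must be > 0")
  structure(list(peak_latencies = peak_latencies,
                 peak_amplitudes = peak_amplitudes,
                 peak_widths = peak_widths,
                 rate = rate),
            class = "errp_template_params")
}

#' Render the ErrP template waveform
#'
#' Evaluates the sum of signed Gaussian bumps on the sample grid
#' `t = (0:(n-1)) / rate` with `n = round(duration * rate)`.
#'
#' @param params an [errp_template_params()] object.
#' @param duration waveform duration in seconds; must cover every peak plus
#'   three standard deviations of the widest bump.
#' @return Numeric vector of microvolt values, length `round(duration * rate)`.
#' @export
errp_template <- function(params, duration) {
  stopifnot(inherits(params, "errp_template_params"))
  if (any(params$peak_latencies >= duration))
    stop("peak latency outside the requested duration")
  if (duration < max(params$peak_latencies) + 3 * max(params$peak_widths))
    stop("duration must be >= max latency + 3 * max width")
  n <- round(duration * params$rate)
  t <- (seq_len(n) - 1) / params$rate
  w <- numeric(n)
  for (k in seq_along(params$peak_latencies)) {
    w <- w + params$peak_amplitudes[k] *
      exp(-0.5 * ((t - params$peak_latencies[k]) / params$peak_widths[k])^2)
  }
  w
}

#' Simulation configuration
#'
#' @param n_trials number of feedback events to simulate (>= 1).
#' @param error_rate probability that a trial is an error trial, in `[0, 1]`.
#'   The monitoring paradigms this emulates used 20% and 30%.
#' @param channels 10-20 channel labels (unique); default the 9-channel
#'   frontocentral grid of [channel_group()] `"D"`.
#' @param rate sampling rate in Hz (default 512).
#' @param noise_sd background noise standard deviation in microvolts. The
#'   default 6 puts the single-trial template peak (|-6| microvolts at FCz)
#'   at SNR ~ 1, a realistic single-trial regime.
#' @param pink_noise_fraction fraction of noise variance carried by 1/f
#'   (pink) noise, the rest being white, in `[0, 1]`.
#' @param artifact_rate per-trial probability of an ocular (blink) transient
#'   on frontal channels (default 0).
#' @param correct_amplitude scale of an optional small feedback deflection on
#'   correct trials (fraction of the error template; default 0 = off).
#' @param seed integer seed; all simulator randomness derives from it.
#' @param topography named gain vector (default [default_topography()] over
#'   `channels`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_trials, error_rate, channels = channel_group("D"),
                       rate = 512, noise_sd = 6, pink_noise_fraction = 0.5,
                       artifact_rate = 0, correct_amplitude = 0, seed = 1,
                       topography = NULL) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  channels <- toupper(channels)
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (rate <= 0) stop("rate must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (pink_noise_fraction < 0 || pink_noise_fraction > 1)
    stop("pink_noise_fraction must be in [0, 1]")
  if (artifact_rate < 0 || artifact_rate > 1)
    stop("artifact_rate must be in [0, 1]")
  if (is.null(topography)) topography <- default_topography(channels)
  structure(list(n_trials = as.integer(n_trials), error_rate = error_rate,
                 channels = channels, rate = rate, noise_sd = noise_sd,
                 pink_noise_fraction = pink_noise_fraction,
                 artifact_rate = artifact_rate,
                 correct_amplitude = correct_amplitude,
                 seed = as.integer(seed), topography = topography),
            class = "sim_config")
}

# Derived per-trial sub-seed so that partial regeneration (or a different
# trial count) leaves earlier trials' noise untouched. Kept below 2^31 - 1.
sub_seed <- function(seed, i) as.integer((as.double(seed) * 48271 + i) %% 2147483629)

# 1/f-amplitude ("pink") noise via spectral shaping, unit variance.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  sp <- stats::fft(white)
  f <- c(1, seq_len(n - 1))              # guard DC
  f <- pmin(f, n - f)                    # two-sided frequency index
  sp <- sp / sqrt(f)
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# Background noise trace: mix of pink and white, sd = noise_sd.
noise_trace <- function(n, noise_sd, pink_fraction) {
  if (noise_sd == 0) return(numeric(n))
  p <- if (pink_fraction > 0) pink_noise(n) else numeric(n)
  w <- if (pink_fraction < 1) stats::rnorm(n) else numeric(n)
  noise_sd * (sqrt(pink_fraction) * p + sqrt(1 - pink_fraction) * w)
}

# One blink transient: half-sine of ~0.3-1 s duration (0.5-2 Hz content),
# strongest frontally, sign-positive as in EOG-contaminated EEG.
blink_transient <- function(n, rate, amplitude = 80) {
  dur <- stats::runif(1, 0.3, 1.0)
  len <- min(n, round(dur * rate))
  start <- sample.int(max(1, n - len + 1), 1)
  tr <- numeric(n)
  tr[start:(start + len - 1)] <- amplitude * sin(pi * seq(0, 1, length.out = len))
  tr
}

is_frontal <- function(channels) grepl("^(FP|AF|F)[0-9Z]", channels)

#' Simulate an epoched ErrP data set
#'
#' Draws i.i.d. Bernoulli(`error_rate`) labels, then builds each trial as
#' background noise (pink + white) on every channel; error trials
#' additionally receive the ErrP template scaled by the channel's scalp gain,
#' time-locked to feedback onset (t = 0, i.e. 0.2 s into the 1 s epoch).
#' Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param template an [errp_template_params()]; defaults to the standard
#'   triphasic complex.
#' @param window epoch window in seconds relative to feedback, default
#'   `c(-0.2, 0.8)`.
#' @return An `eeg_epochs` object (see [eeg_epochs()]).
#' @export
#' @examples
#' ep <- simulate_epochs(sim_config(n_trials = 20, error_rate = 0.2, seed = 1))
#' table(ep$labels)
simulate_epochs <- function(cfg, template = errp_template_params(rate = cfg$rate),
                            window = c(-0.2, 0.8)) {
  stopifnot(inherits(cfg, "sim_config"))
  n_samp <- round((window[2] - window[1]) * cfg$rate)
  pre <- round(-window[1] * cfg$rate)
  set.seed(cfg$seed)
  labels <- stats::rbinom(cfg$n_trials, 1, cfg$error_rate)
  tmpl <- errp_template(template, duration = window[2])
  gains <- vapply(cfg$channels, scalp_gain, numeric(1),
                  topography = cfg$topography)
  data <- array(0, dim = c(cfg$n_trials, length(cfg$channels), n_samp),
                dimnames = list(NULL, cfg$channels, NULL))
  frontal <- is_frontal(cfg$channels)
  for (i in seq_len(cfg$n_trials)) {
    set.seed(sub_seed(cfg$seed, i))
    for (ch in seq_along(cfg$channels)) {
      x <- noise_trace(n_samp, cfg$noise_sd, cfg$pink_noise_fraction)
      amp <- if (labels[i] == 1) gains[ch] else cfg$correct_amplitude * gains[ch]
      if (amp != 0) {
        idx <- (pre + 1):n_samp
        x[idx] <- x[idx] + amp * tmpl[seq_along(idx)]
      }
      data[i, ch, ] <- x
    }
    if (cfg$artifact_rate > 0) {
      # separate stream so toggling artifacts never perturbs the noise draws
      set.seed(sub_seed(cfg$seed, 50000L + i))
      if (stats::runif(1) < cfg$artifact_rate) {
        btr <- blink_transient(n_samp, cfg$rate)
        for (ch in which(frontal)) data[i, ch, ] <- data[i, ch, ] + btr
      }
    }
  }
  eeg_epochs(data, labels, rate = cfg$rate, window = window,
             channel_names = cfg$channels)
}

#' Simulate a continuous multichannel recording
#'
#' Lays the trials of [simulate_epochs()] semantics onto a continuous noise
#' background: events are spaced `inter_trial` seconds apart, each error
#' event adds the scalp-weighted template at its onset. Epoching the result
#' with [extract_epochs()] recovers the same labels in the same order.
#'
#' @inheritParams simulate_epochs
#' @param inter_trial event spacing in seconds, must be >= 1.
#' @return An `eeg_recording` object (see [eeg_recording()]).
#' @export
simulate_recording <- function(cfg, template = errp_template_params(rate = cfg$rate),
                               inter_trial = 2) {
  stopifnot(inherits(cfg, "sim_config"))
  if (inter_trial < 1) stop("inter_trial must be >= 1 second")
  rate <- cfg$rate
  lead <- 1                                     # seconds before first event
  total <- lead + cfg$n_trials * inter_trial + 1
  n <- round(total * rate)
  set.seed(cfg$seed)
  labels <- stats::rbinom(cfg$n_trials, 1, cfg$error_rate)
  onsets <- round((lead + (seq_len(cfg$n_trials) - 1) * inter_trial) * rate)
  tmpl <- errp_template(template, duration = 0.8)
  gains <- vapply(cfg$channels, scalp_gain, numeric(1),
                  topography = cfg$topography)
  frontal <- is_frontal(cfg$channels)
  data <- matrix(0, nrow = length(cfg$channels), ncol = n,
                 dimnames = list(cfg$channels, NULL))
  for (ch in seq_along(cfg$channels)) {
    set.seed(sub_seed(cfg$seed, 10000 + ch))
    data[ch, ] <- noise_trace(n, cfg$noise_sd, cfg$pink_noise_fraction)
  }
  for (i in seq_len(cfg$n_trials)) {
    amp <- if (labels[i] == 1) 1 else cfg$correct_amplitude
    if (amp != 0) {
      idx <- onsets[i] + seq_along(tmpl)        # 1-based: onset sample + 0..
      data[, idx] <- data[, idx] + outer(amp * gains, tmpl)
    }
    set.seed(sub_seed(cfg$seed, 20000 + i))
    if (cfg$artifact_rate > 0 && stats::runif(1) < cfg$artifact_rate) {
      seg <- onsets[i] + seq_len(round(inter_trial * rate))
      seg <- seg[seg <= n]
      btr <- blink_transient(length(seg), rate)
      data[frontal, seg] <- sweep(data[frontal, seg, drop = FALSE], 2, btr, "+")
    }
  }
  events <- data.frame(sample = onsets,
                       label = ifelse(labels == 1, "error", "correct"),
                       stringsAsFactors = FALSE)
  eeg_recording(data, rate = rate, channel_names = cfg$channels,
                events = events)
}
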