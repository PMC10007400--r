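#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean across channels: the
#' standard spatial filter for reducing common-mode noise before ErrP
#' analysis. Idempotent.
#'
#' @param rec an `eeg_recording`.
#' @return The re-referenced `eeg_recording`.
#' @export
apply_car <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2)
    stop("common average reference needs at least 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data), "-")
  rec
}

# ---- Butterworth band-pass design (bilinear transform) ----------------------

# Analog Butterworth low-pass prototype poles (cutoff 1 rad/s).
butter_proto_poles <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))
}

# Order-n Butterworth band-pass as digital (b, a): LP prototype ->
# band-pass transform -> bilinear transform with pre-warping.
butter_bandpass <- function(low, high, rate, order = 3) {
  if (low <= 0 || high <= low || high >= rate / 2)
    stop("band edges must satisfy 0 < low < high < rate/2")
  if (order < 1) stop("order must be >= 1")
  fs2 <- 2 * rate
  w1 <- fs2 * tan(pi * low / rate)
  w2 <- fs2 * tan(pi * high / rate)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  p <- butter_proto_poles(order)
  # s_lp -> (s^2 + w0^2) / (bw * s): each prototype pole yields two poles.
  disc <- sqrt((p * bw)^2 / 4 - w0^2 + 0i)
  poles <- c(p * bw / 2 + disc, p * bw / 2 - disc)
  zeros <- rep(0 + 0i, order)            # n zeros at s = 0 (and n at infinity)
  gain <- bw^order
  # Bilinear transform z = (fs2 + s) / (fs2 - s).
  zd <- (fs2 + zeros) / (fs2 - zeros)
  pd <- (fs2 + poles) / (fs2 - poles)
  gd <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))  # degree match at z = -1
  b <- Re(gd * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# Monic polynomial coefficients from roots (descending powers).
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs * ri)
  coefs
}

# Steady-state initial filter conditions (the classic lfilter_zi construction):
# with state zi * x0 a constant input x0 produces the steady-state output
# immediately, eliminating start-up transients.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b))) / a[1]
  a <- c(a, numeric(n - length(a))) / a[1]
  comp <- matrix(0, n - 1, n - 1)              # companion matrix of a
  comp[1, ] <- -a[-1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  solve(diag(n - 1) - t(comp), b[-1] - a[-1] * b[1])
}

# Zero-phase filtering: odd extension at both ends, forward pass with
# steady-state initial conditions, reverse pass, trim.
filtfilt_1d <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1, 3 * (max(length(a), length(b)) - 1) * 4)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  zi <- lfilter_zi(b, a)
  y <- cpp_iir_filter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- rev(cpp_iir_filter(b, a, y, zi * y[1]))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs an order-`order` Butterworth band-pass (bilinear transform) and
#' applies it forward and backward (zero phase) to every channel. The default
#' band is 1-10 Hz and the default order 3, the standard offline ErrP
#' setting; both are configurable.
#'
#' @param rec an `eeg_recording`.
#' @param low,high band edges in Hz, `0 < low < high < rate/2`.
#' @param order filter order (default 3).
#' @return The filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low = 1, high = 10, order = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  ba <- butter_bandpass(low, high, rec$rate, order)
  for (ch in seq_len(nrow(rec$data)))
    rec$data[ch, ] <- filtfilt_1d(ba$b, ba$a, rec$data[ch, ])
  rec
}

# ---- ICA artifact removal ---------------------------------------------------

# Symmetric FastICA with tanh contrast on whitened data.
# X: components-in-rows matrix (channels x samples), already centered.
fastica_decompose <- function(X, n_comp = nrow(X), max_iter = 200,
                              tol = 1e-4, seed = 1) {
  Xc <- X - rowMeans(X)
  sv <- svd(Xc / sqrt(ncol(Xc)))
  K <- diag(1 / sv$d[seq_len(n_comp)], n_comp) %*%
    t(sv$u[, seq_len(n_comp), drop = FALSE])       # whitening matrix
  Z <- K %*% Xc
  set.seed(seed)
  W <- matrix(stats::rnorm(n_comp^2), n_comp)
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WX <- W %*% Z
    G <- tanh(WX)
    gp <- rowMeans(1 - G^2)
    W1 <- G %*% t(Z) / ncol(Z) - diag(gp, n_comp) %*% W
    W1 <- sym_decorrelate(W1)
    if (max(abs(abs(rowSums(W1 * W)) - 1)) < tol) { W <- W1; break }
    W <- W1
  }
  unmix <- W %*% K                     # sources = unmix %*% Xc
  mix <- sv$u[, seq_len(n_comp), drop = FALSE] %*%
    diag(sv$d[seq_len(n_comp)], n_comp) %*% t(W)   # Xc ~ mix %*% sources
  list(sources = unmix %*% Xc, mixing = mix, means = rowMeans(X))
}

sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
                     nrow(W)) %*% t(e$vectors) %*% W
}

#' ICA-based ocular artifact removal
#'
#' With `method = "ica"`, decomposes the recording with FastICA, flags
#' components whose time course correlates (|r| > `threshold`) with a
#' low-frequency (0.5-2 Hz) frontal reference — the mean of the available
#' FZ/F1/F2 channels — and reconstructs the recording without them. Blink
#' activity is frontal and slow, so this targets exactly the eye-artifact
#' subspace. `method = "none"` is the identity.
#'
#' @param rec an `eeg_recording`.
#' @param method `"none"` (default) or `"ica"`.
#' @param threshold absolute correlation above which a component is rejected.
#' @param seed seed for the FastICA initial rotation.
#' @return The cleaned `eeg_recording`, with attribute `"rejected"` giving
#'   the number of removed components (for `"ica"`).
#' @export
remove_artifacts <- function(rec, method = c("none", "ica"), threshold = 0.7,
                             seed = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  method <- match.arg(method)
  if (method == "none") return(rec)
  if (nrow(rec$data) < 4)
    stop("ICA artifact removal needs at least 4 channels")
  if (ncol(rec$data) < 30 * rec$rate)
    stop("ICA artifact removal needs at least 30 s of data")
  frontal <- rec$channel_names %in% c("FZ", "F1", "F2")
  if (!any(frontal)) frontal <- is_frontal(rec$channel_names)
  if (!any(frontal))
    stop("no frontal channels available for the blink reference")
  ref <- colMeans(rec$data[frontal, , drop = FALSE])
  ba <- butter_bandpass(0.5, 2, rec$rate, order = 2)
  ref <- filtfilt_1d(ba$b, ba$a, ref)
  dec <- fastica_decompose(rec$data, seed = seed)
  r <- abs(apply(dec$sources, 1, stats::cor, y = ref))
  keep <- r <= threshold
  clean <- dec$mixing[, keep, drop = FALSE] %*%
    dec$sources[keep, , drop = FALSE] + dec$means
  dimnames(clean) <- dimnames(rec$data)
  rec$data <- clean
  attr(rec, "rejected") <- sum(!keep)
  rec
}

#' Extract epochs around feedback events
#'
#' Cuts one `[t0, t1]` window per event (default -0.2 to +0.8 s, i.e. 1 s:
#' 512 samples at 512 Hz). Epoch sample 1 corresponds to event time + t0.
#' Events too close to a recording edge are dropped with a warning; the
#' number of dropped events is attached as attribute `"dropped"`.
#'
#' @param rec an `eeg_recording`.
#' @param window length-2 numeric window in seconds relative to the event.
#' @return An `eeg_epochs` object (labels copied from the retained events,
#'   in event order).
#' @export
extract_epochs <- function(rec, window = c(-0.2, 0.8)) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (window[1] >= window[2]) stop("window must satisfy t0 < t1")
  n_samp <- round((window[2] - window[1]) * rec$rate)
  pre <- round(-window[1] * rec$rate)
  total <- ncol(rec$data)
  starts <- rec$events$sample - pre + 1          # 1-based first sample
  ok <- starts >= 1 & (starts + n_samp - 1) <= total
  if (any(!ok))
    warning(sum(!ok), " event(s) too close to the recording edge were dropped")
  if (!any(ok)) stop("no events with a complete epoch window")
  keep <- which(ok)
  data <- array(0, dim = c(length(keep), nrow(rec$data), n_samp))
  for (j in seq_along(keep)) {
    i <- keep[j]
    data[j, , ] <- rec$data[, starts[i]:(starts[i] + n_samp - 1)]
  }
  ep <- eeg_epochs(data, as.integer(rec$events$label[keep] == "error"),
                   rate = rec$rate, window = window,
                   channel_names = rec$channel_names)
  attr(ep, "dropped") <- sum(!ok)
  ep
}

#' Min-max normalize epochs
#'
#' Per trial and per channel, maps the trace to `[0, 1]` via
#' `(x - min) / (max - min)`, the scaling the image renderer expects. A
#' constant trace (max == min) maps to 0.5 everywhere (mid-gray baseline)
#' with a warning. Idempotent on non-constant traces.
#'
#' @param ep an `eeg_epochs` object.
#' @return The normalized `eeg_epochs` (`normalized = TRUE`).
#' @export
normalize_epochs <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$data)
  n_const <- 0L
  for (i in seq_len(d[1])) for (ch in seq_len(d[2])) {
    x <- ep$data[i, ch, ]
    rng <- range(x)
    if (rng[1] == rng[2]) {
      ep$data[i, ch, ] <- 0.5
      n_const <- n_const + 1L
    } else {
      ep$data[i, ch, ] <- (x - rng[1]) / (rng[2] - rng[1])
    }
  }
  if (n_const > 0)
    warning(n_const, " constant trace(s) mapped to 0.5")
  ep$normalized <- TRUE
  ep
}

#' Full preprocessing pipeline
#'
#' Applies, in order: common average reference, zero-phase Butterworth
#' band-pass, optional ICA artifact removal, epoching and min-max
#' normalization. The order is fixed; the settings used are recorded in the
#' result's `"preprocess"` attribute.
#'
#' @param rec an `eeg_recording`.
#' @param band length-2 band edges in Hz (default `c(1, 10)`).
#' @param order Butterworth order (default 3).
#' @param ica logical: run ICA artifact removal (default `FALSE`; synthetic
#'   data without artifacts does not need it).
#' @param window epoch window in seconds (default `c(-0.2, 0.8)`).
#' @return A normalized `eeg_epochs` object.
#' @export
#' @examples
#' rec <- simulate_recording(sim_config(n_trials = 5, error_rate = 0.2,
#'                                      channels = c("FCZ", "CZ"), seed = 1))
#' ep <- preprocess(rec)
preprocess <- function(rec, band = c(1, 10), order = 3, ica = FALSE,
                       window = c(-0.2, 0.8)) {
  rec <- apply_car(rec)
  rec <- bandpass_filter(rec, band[1], band[2], order)
  if (ica) rec <- remove_artifacts(rec, "ica")
  ep <- extract_epochs(rec, window)
  ep <- normalize_epochs(ep)
  attr(ep, "preprocess") <- list(car = TRUE, band = band, order = order,
                                 ica = ica, window = window)
  ep
}
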