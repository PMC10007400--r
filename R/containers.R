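#' Continuous multichannel EEG recording
#'
#' A light container for a continuous recording: a channels x samples matrix
#' of microvolt values, the sampling rate, channel labels and feedback events.
#' Event sample indices are 0-based offsets into the recording (the sample at
#' index `s` is column `s + 1` of `data`).
#'
#' @param data numeric matrix, channels x samples.
#' @param rate sampling rate in Hz.
#' @param channel_names unique 10-20 labels, one per row of `data`.
#' @param events data.frame with columns `sample` (0-based integer) and
#'   `label` (`"correct"` or `"error"`).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channel_names, events) {
  data <- as.matrix(data)
  channel_names <- toupper(channel_names)
  if (!all(is.finite(data))) stop("recording contains non-finite values")
  if (rate <= 0) stop("rate must be > 0")
  if (nrow(data) != length(channel_names))
    stop("channel_names length must match nrow(data)")
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  stopifnot(is.data.frame(events), all(c("sample", "label") %in% names(events)))
  if (nrow(events) &&
      (min(events$sample) < 0 || max(events$sample) >= ncol(data)))
    stop("event sample indices must lie within [0, samples)")
  if (!all(events$label %in% c("correct", "error")))
    stop("event labels must be 'correct' or 'error'")
  events$sample <- as.integer(events$sample)
  rownames(data) <- channel_names
  structure(list(data = data, rate = rate, channel_names = channel_names,
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  cat(sprintf("  channels: %s\n", paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  events: %d (%d error, %d correct)\n", nrow(x$events),
              sum(x$events$label == "error"), sum(x$events$label == "correct")))
  invisible(x)
}

#' Epoched single-trial EEG
#'
#' Trials x channels x samples array with binary labels (1 = error trial,
#' 0 = correct trial) and the epoch window relative to feedback onset.
#'
#' @param data numeric array, trials x channels x samples.
#' @param labels integer vector in `{0, 1}`, one per trial.
#' @param rate sampling rate in Hz.
#' @param window length-2 numeric, seconds relative to feedback onset
#'   (default `c(-0.2, 0.8)`, i.e. 1 s total).
#' @param channel_names unique labels, one per channel slice.
#' @param normalized logical flag recording whether min-max normalization has
#'   been applied.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, labels, rate, window = c(-0.2, 0.8),
                       channel_names, normalized = FALSE) {
  stopifnot(length(dim(data)) == 3)
  channel_names <- toupper(channel_names)
  labels <- as.integer(labels)
  if (dim(data)[1] != length(labels))
    stop("labels length must match the number of trials")
  if (dim(data)[2] != length(channel_names))
    stop("channel_names length must match the number of channels")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 (correct) or 1 (error)")
  if (dim(data)[3] != round((window[2] - window[1]) * rate))
    stop("sample count does not match round((t1 - t0) * rate)")
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  dimnames(data) <- list(NULL, channel_names, NULL)
  structure(list(data = data, labels = labels, rate = rate, window = window,
                 channel_names = channel_names, normalized = normalized),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$rate))
  cat(sprintf("  window: [%g, %g] s; labels: %d error / %d correct; normalized: %s\n",
              x$window[1], x$window[2], sum(x$labels == 1), sum(x$labels == 0),
              x$normalized))
  invisible(x)
}

#' Number of trials
#' @param ep an `eeg_epochs` object.
#' @return Integer trial count.
#' @export
n_trials <- function(ep) dim(ep$data)[1]

# ---- plain-text array container (TSV data + JSON sidecar) -------------------

#' Write / read an epoch set as a plain-text container
#'
#' The data cube is flattened to a TSV (one row per trial x channel, samples
#' in columns) next to a JSON sidecar holding labels, rate, window and
#' channel names. A matching reader restores the `eeg_epochs` object exactly
#' (up to text round-off at 12 significant digits).
#'
#' @param ep an `eeg_epochs` object.
#' @param path basename for the two files (`<path>.tsv`, `<path>.json`).
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()` returns
#'   the restored `eeg_epochs`.
#' @export
write_epochs <- function(ep, path) {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$data)
  flat <- matrix(aperm(ep$data, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  utils::write.table(format(flat, digits = 12, trim = TRUE, scientific = TRUE),
                     paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- list(n_trials = d[1], n_channels = d[2], n_samples = d[3],
               labels = ep$labels, rate = ep$rate, window = ep$window,
               channel_names = ep$channel_names, normalized = ep$normalized)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t"))
  data <- aperm(array(t(flat), dim = c(meta$n_samples, meta$n_channels,
                                       meta$n_trials)), c(3, 2, 1))
  eeg_epochs(data, meta$labels, rate = meta$rate, window = meta$window,
             channel_names = meta$channel_names, normalized = meta$normalized)
}

#' Write / read a continuous recording as a plain-text container
#'
#' @param rec an `eeg_recording` object.
#' @param path basename for the two files (`<path>.tsv`, `<path>.json`).
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   the restored `eeg_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(format(rec$data, digits = 12, trim = TRUE,
                            scientific = TRUE),
                     paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- list(rate = rec$rate, channel_names = rec$channel_names,
               event_sample = rec$events$sample, event_label = rec$events$label)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t"))
  dimnames(data) <- NULL
  eeg_recording(data, rate = meta$rate, channel_names = meta$channel_names,
                events = data.frame(sample = meta$event_sample,
                                    label = meta$event_label,
                                    stringsAsFactors = FALSE))
}
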