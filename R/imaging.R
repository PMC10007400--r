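#' Rasterize a normalized trace into a 224 x 224 grayscale image
#'
#' Draws the single-trial waveform exactly as a plotting library would, but
#' with deterministic 1-pixel Bresenham rasterization and no anti-aliasing:
#' trace pixels are 0 (black), background 255 (white), nothing else. Time
#' maps left to right across all columns; amplitude maps bottom-up, value 0
#' at the bottom row and 1 at the top row (no axes, ticks or margins). The
#' polyline between consecutive samples is interpolated, so every column in
#' the time range contains at least one trace pixel.
#'
#' @param trace numeric vector in `[0, 1]`, length >= 2 (normalize first).
#' @param size image side in pixels (default 224).
#' @param baseline_row optional bottom-up row (0-based) to pin the value 0.5
#'   to, mimicking a plot whose origin sits mid-axis; values are then mapped
#'   `round(baseline_row + (v - 0.5) * (size - 1))` and clipped. Default
#'   `NULL` uses the full-range mapping `round(v * (size - 1))`.
#' @return An integer `size` x `size` matrix of class `eeg_image` (row 1 is
#'   the top of the image), values in `{0, 255}`.
#' @export
#' @examples
#' img <- render_trace_image(seq(0, 1, length.out = 512))
#' dim(img)
render_trace_image <- function(trace, size = 224, baseline_row = NULL) {
  if (length(trace) < 2) stop("trace must have at least 2 samples")
  if (any(!is.finite(trace)) || any(trace < 0) || any(trace > 1))
    stop("trace values must be finite and in [0, 1]; normalize first")
  L <- length(trace)
  xs <- round((seq_len(L) - 1) * (size - 1) / (L - 1))      # 0-based columns
  if (is.null(baseline_row)) {
    ys <- round(trace * (size - 1))                          # 0-based, bottom-up
  } else {
    ys <- round(baseline_row + (trace - 0.5) * (size - 1))
    ys <- pmin(pmax(ys, 0), size - 1)
  }
  img <- matrix(255L, size, size)
  for (i in seq_len(L - 1)) {
    px <- bresenham(xs[i], ys[i], xs[i + 1], ys[i + 1])
    img[cbind(size - px[, 2], px[, 1] + 1)] <- 0L            # flip to top-down
  }
  class(img) <- c("eeg_image", class(img))
  img
}

# Bresenham line from (x0,y0) to (x1,y1), 0-based integer pixel coords.
bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  n <- max(dx, -dy) + 1L
  px <- integer(n); py <- integer(n)
  x <- x0; y <- y0
  for (k in seq_len(n)) {
    px[k] <- x; py[k] <- y
    if (x == x1 && y == y1) break
    e2 <- 2 * err
    if (e2 >= dy) { err <- err + dy; x <- x + sx }
    if (e2 <= dx) { err <- err + dx; y <- y + sy }
  }
  cbind(px[seq_len(k)], py[seq_len(k)])
}

#' @export
print.eeg_image <- function(x, ...) {
  cat(sprintf("<eeg_image> %d x %d, %d trace pixels", nrow(x), ncol(x),
              sum(x == 0L)))
  prov <- attr(x, "provenance")
  if (!is.null(prov)) cat(sprintf(" (trial %d, channel %s)", prov$trial, prov$channel))
  cat("\n")
  invisible(x)
}

#' Render every trial of one channel as images
#'
#' @param ep a normalized `eeg_epochs` object.
#' @param channel channel label present in `ep$channel_names`.
#' @param size image side in pixels (default 224).
#' @param baseline_row see [render_trace_image()].
#' @return A list of `eeg_image` matrices, one per trial in trial order, each
#'   carrying a `provenance` attribute `(trial, channel)`; the trial labels
#'   are attached as attribute `"labels"`.
#' @export
render_epochs <- function(ep, channel, size = 224, baseline_row = NULL) {
  stopifnot(inherits(ep, "eeg_epochs"))
  channel <- toupper(channel)
  if (!channel %in% ep$channel_names)
    stop("channel '", channel, "' not present in the epoch set")
  if (!ep$normalized)
    stop("epochs must be min-max normalized before rendering")
  ch <- match(channel, ep$channel_names)
  imgs <- vector("list", n_trials(ep))
  for (i in seq_along(imgs)) {
    img <- render_trace_image(ep$data[i, ch, ], size = size,
                              baseline_row = baseline_row)
    attr(img, "provenance") <- list(trial = i, channel = channel)
    imgs[[i]] <- img
  }
  attr(imgs, "labels") <- ep$labels
  imgs
}

# Stack a list of images into the H x W x N pixel array the network consumes,
# scaled to [0, 1] (pixel / 255).
images_to_array <- function(imgs) {
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  x <- array(0, dim = c(H, W, length(imgs)))
  for (i in seq_along(imgs)) x[, , i] <- imgs[[i]] / 255
  x
}

#' Write / read an image as plain-text PGM (P2)
#'
#' Plain-text portable graymap: readable by any image tool, no binary
#' dependency needed.
#'
#' @param img an `eeg_image` (or any integer matrix in 0..255).
#' @param path output file path.
#' @return `write_pgm()` returns `path` invisibly; `read_pgm()` the image
#'   matrix.
#' @export
write_pgm <- function(img, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  utils::write.table(unclass(img), con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  stopifnot(lines[1] == "P2")
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- scan(text = paste(lines[-(1:3)], collapse = "\n"), quiet = TRUE)
  img <- matrix(as.integer(vals), nrow = dims[2], ncol = dims[1], byrow = TRUE)
  class(img) <- c("eeg_image", class(img))
  img
}
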