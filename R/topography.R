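#' Schematic 10-20 electrode positions
#'
#' Returns approximate 2D scalp coordinates for the extended 10-20 montage,
#' on a unit-ish grid with the vertex (Cz) at the origin, x increasing to the
#' right and y increasing toward the front. The coordinates are schematic:
#' they preserve neighbourhood ordering (which is all the scalp-attenuation
#' model needs), not true geodesic distances.
#'
#' @return A data.frame with columns `channel`, `x`, `y`.
#' @export
#' @examples
#' head(electrode_positions())
electrode_positions <- function() {
  rows <- c(FP = 0.9, AF = 0.7, F = 0.5, FC = 0.25, C = 0,
            CP = -0.25, P = -0.5, PO = -0.7, O = -0.9)
  xs <- c(0, 0.15, 0.35, 0.55, 0.75)  # z, 1/2, 3/4, 5/6, 7/8
  out <- list()
  for (r in names(rows)) {
    labs <- c(paste0(r, "Z"),
              paste0(r, c(1, 3, 5, 7)), paste0(r, c(2, 4, 6, 8)))
    x <- c(0, -xs[2:5], xs[2:5])
    out[[r]] <- data.frame(channel = labs, x = x, y = rows[[r]],
                           stringsAsFactors = FALSE)
  }
  pos <- do.call(rbind, out)
  rownames(pos) <- NULL
  pos
}

#' Scalp attenuation topography for the ErrP template
#'
#' The error-related potential is generated in the anterior cingulate cortex
#' and is strongest at FCz, weakening gradually at surrounding frontocentral
#' electrodes. This builds a channel -> gain mapping with gain 1 at FCz,
#' exponential decay `exp(-d / decay)` in schematic electrode distance `d`
#' from FCz, and gain 0 beyond `support` (e.g. occipital channels).
#'
#' @param channels character vector of 10-20 labels (case-insensitive).
#' @param decay e-folding distance of the exponential decay, in units of
#'   [electrode_positions()] (default 0.35: next-ring neighbours keep roughly
#'   half the FCz amplitude).
#' @param support radius beyond which the gain is exactly 0 (default 0.8).
#' @return Named numeric vector of gains in `[0, 1]`, one per channel.
#' @export
#' @examples
#' default_topography(c("FCZ", "CZ", "OZ"))
default_topography <- function(channels, decay = 0.35, support = 0.8) {
  stopifnot(decay > 0, support > 0)
  pos <- electrode_positions()
  channels <- toupper(channels)
  miss <- setdiff(channels, pos$channel)
  if (length(miss))
    stop("unknown 10-20 channel label(s): ", paste(miss, collapse = ", "))
  ref <- pos[pos$channel == "FCZ", ]
  i <- match(channels, pos$channel)
  d <- sqrt((pos$x[i] - ref$x)^2 + (pos$y[i] - ref$y)^2)
  g <- ifelse(d > support, 0, exp(-d / decay))
  names(g) <- channels
  g
}

#' Gain of one channel under a topography
#'
#' @param channel a single 10-20 label.
#' @param topography named gain vector, e.g. from [default_topography()].
#' @return The gain in `[0, 1]`.
#' @export
scalp_gain <- function(channel, topography) {
  stopifnot(is.character(channel), length(channel) == 1)
  channel <- toupper(channel)
  if (!channel %in% names(topography)) {
    if (!channel %in% electrode_positions()$channel)
      stop("unknown 10-20 channel label: ", channel)
    stop("channel '", channel, "' not present in the topography")
  }
  unname(topography[[channel]])
}

#' Frontocentral channel groups
#'
#' Named groups of anterior-cingulate-area channels centred on FCz, used to
#' choose which per-channel classifiers enter the ensemble. Group A is the
#' classic FCz + Cz pair and group D is the 3 x 3 frontocentral grid
#' (F1, FZ, F2, FC1, FCZ, FC2, C1, CZ, C2); groups B, C and E are
#' documented reconstructions (3, 5 and 15 channels) that grow the grid
#' outward, and can be overridden by passing an explicit channel vector
#' wherever a group name is accepted.
#'
#' @param name one of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`.
#' @return Character vector of channel labels.
#' @export
#' @examples
#' channel_group("D")
channel_group <- function(name = c("D", "A", "B", "C", "E")) {
  name <- match.arg(name)
  groups <- list(
    A = c("FCZ", "CZ"),
    B = c("FZ", "FCZ", "CZ"),
    C = c("FZ", "FC1", "FCZ", "FC2", "CZ"),
    D = c("F1", "FZ", "F2", "FC1", "FCZ", "FC2", "C1", "CZ", "C2"),
    E = c("F3", "F1", "FZ", "F2", "F4",
          "FC3", "FC1", "FCZ", "FC2", "FC4",
          "C3", "C1", "CZ", "C2", "C4"))
  groups[[name]]
}
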