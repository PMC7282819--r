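# Temporally color-coded maximum projection ("time projection") rendering:
# each pixel is colored by WHEN its background-subtracted signal peaked
# within a window (red at the window start through purple at the end) and
# its brightness scales with the peak amplitude.

#' Temporally color-coded maximum projection
#'
#' For every pixel the frame of maximum background-subtracted intensity
#' within `[t_start_ms, t_end_ms]` is found; that time is mapped linearly
#' onto a red-to-purple hue ramp (HSV hue 0 to 0.8), brightness is scaled
#' by the maximum's amplitude, and pixels whose amplitude stays below the
#' noise floor are rendered black.
#'
#' @param movie a [glu_movie()].
#' @param t_start_ms,t_end_ms window limits in ms from recording start
#'   (must contain at least one frame center).
#' @param baseline_frame_count frames averaged for the background estimate.
#' @param noise_floor amplitude below which a pixel stays black; `NULL`
#'   (default) uses 4x the MAD of the windowed background-subtracted
#'   intensities.
#' @return `height x width x 3` RGB array in `[0, 1]`, with attributes
#'   `peak_time_ms` (matrix) and `noise_floor`.
#' @export
time_projection <- function(movie, t_start_ms, t_end_ms,
                            baseline_frame_count = 45L, noise_floor = NULL) {
  if (t_end_ms <= t_start_ms) stop("empty window: t_end_ms must exceed t_start_ms")
  tc <- frame_times(movie)
  sel <- which(tc >= t_start_ms & tc <= t_end_ms)
  if (!length(sel)) stop("window contains no frames")
  base <- baseline_projection(movie, baseline_frame_count)
  d <- dim(movie$frames)
  sub <- movie$frames[sel, , , drop = FALSE] -
    array(rep(base, each = length(sel)), dim = c(length(sel), d[2], d[3]))
  peak_idx <- apply(sub, c(2, 3), which.max)
  amp <- apply(sub, c(2, 3), max)
  if (is.null(noise_floor)) noise_floor <- 4 * stats::mad(sub)
  frac <- (tc[sel][peak_idx] - t_start_ms) / (t_end_ms - t_start_ms)
  frac <- matrix(pmin(pmax(frac, 0), 1), d[2], d[3])
  v <- amp / max(amp, na.rm = TRUE)
  v[!is.finite(v)] <- 0
  v <- pmin(pmax(v, 0), 1)
  v[amp < noise_floor] <- 0
  cols <- grDevices::hsv(h = 0.8 * frac, s = 1, v = v)
  rgb <- grDevices::col2rgb(cols) / 255
  out <- array(0, dim = c(d[2], d[3], 3))
  out[, , 1] <- matrix(rgb[1, ], d[2], d[3])
  out[, , 2] <- matrix(rgb[2, ], d[2], d[3])
  out[, , 3] <- matrix(rgb[3, ], d[2], d[3])
  attr(out, "peak_time_ms") <- matrix(tc[sel][peak_idx], d[2], d[3])
  attr(out, "noise_floor") <- noise_floor
  out
}

#' Hue of the time-projection color ramp at a relative time
#'
#' The ramp is a linear HSV sweep from red (hue 0) at the window start to
#' purple (hue 0.8) at the window end; exposed so renderings can be checked
#' against the closed form.
#'
#' @param frac position in the window, 0 (start) to 1 (end).
#' @return HSV hue in `[0, 0.8]`.
#' @export
time_ramp_hue <- function(frac) 0.8 * pmin(pmax(frac, 0), 1)
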