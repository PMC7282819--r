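# Per-ROI trace extraction and dF/F0 normalization.

#' Extract per-ROI mean-intensity traces from a movie
#'
#' `raw[k, t]` is the arithmetic mean of frame `t` over the pixels of ROI
#' `k`. An empty ROI set yields an empty trace set (not an error).
#'
#' @param movie a [glu_movie()].
#' @param rois a `glu_rois` whose label image matches the movie frame shape.
#' @return an object of class `glu_traces`: list with `roi_ids`, `times_ms`
#'   (frame-center times), `raw` (ROI x time matrix), `dff` (`NULL` until
#'   [normalize_dff()]), `f0`, `f0_valid`, `frame_interval_ms`,
#'   `stimulus_time_ms`.
#' @export
extract_traces <- function(movie, rois) {
  lab <- rois$label_image
  d <- dim(movie$frames)
  if (!all(dim(lab) == d[2:3]))
    stop("label image (", paste(dim(lab), collapse = "x"),
         ") does not match movie frame shape (", paste(d[2:3], collapse = "x"), ")")
  ids <- rois$rois$roi_id
  nt <- d[1]
  M <- matrix(movie$frames, nrow = nt)  # frames as rows, pixels as columns
  lv <- as.integer(lab)
  raw <- matrix(numeric(0), nrow = 0, ncol = nt)
  if (length(ids)) {
    raw <- t(vapply(ids, function(k) {
      cols <- which(lv == k)
      if (length(cols) == 1L) M[, cols] else rowMeans(M[, cols, drop = FALSE])
    }, numeric(nt)))
  }
  structure(list(roi_ids = ids,
                 times_ms = (seq_len(nt) - 0.5) * movie$frame_interval_ms,
                 raw = raw, dff = NULL, f0 = NULL, f0_valid = NULL,
                 frame_interval_ms = movie$frame_interval_ms,
                 stimulus_time_ms = movie$stimulus_time_ms),
            class = "glu_traces")
}

#' Normalize traces to dF/F0 against the pre-stimulus baseline
#'
#' `f0` is the per-ROI mean of the raw trace over the first
#' `baseline_frame_count` frames and `dff = (raw - f0) / f0`. ROIs with
#' `f0 <= 0` are flagged (`f0_valid = FALSE`) and should be excluded from
#' peak analysis; [detect_peaks()] does so automatically. Baseline
#' subtraction happens inside the dF/F0 formula per ROI; no separate
#' dark-region background ROI is used.
#'
#' @param traces a `glu_traces` from [extract_traces()].
#' @param baseline_frame_count frames in the baseline window (>= 1, and the
#'   window must precede the stimulus when one is present).
#' @return the trace set with `dff`, `f0` and `f0_valid` filled.
#' @export
normalize_dff <- function(traces, baseline_frame_count = 45L) {
  stopifnot(inherits(traces, "glu_traces"))
  n <- as.integer(baseline_frame_count)
  nt <- ncol(traces$raw)
  if (n < 1L) stop("baseline window is empty")
  if (nrow(traces$raw) > 0 && n > nt)
    stop("baseline window longer than the recording")
  if (!is.null(traces$stimulus_time_ms) &&
      n * traces$frame_interval_ms > traces$stimulus_time_ms)
    warning("baseline window extends past the stimulus")
  if (nrow(traces$raw) == 0L) {
    traces$dff <- traces$raw
    traces$f0 <- numeric(0)
    traces$f0_valid <- logical(0)
    return(traces)
  }
  f0 <- rowMeans(traces$raw[, seq_len(n), drop = FALSE])
  valid <- f0 > 0
  dff <- (traces$raw - f0) / ifelse(f0 > 0, f0, NA_real_)
  if (any(!valid))
    warning(sum(!valid), " ROI(s) with non-positive baseline flagged and ",
            "excluded from peak analysis")
  traces$dff <- dff
  traces$f0 <- f0
  traces$f0_valid <- valid
  traces
}

#' @export
print.glu_traces <- function(x, ...) {
  cat(sprintf("<glu_traces> %d ROI(s) x %d frames (%g ms/frame)%s\n",
              nrow(x$raw), ncol(x$raw), x$frame_interval_ms,
              if (is.null(x$dff)) ", raw only" else ", dF/F0 normalized"))
  invisible(x)
}

#' Export traces as a long-format data frame
#'
#' One row per (ROI, frame) with columns `roi_id`, `time_ms`, `raw` and,
#' when normalized, `dff`.
#'
#' @param traces a `glu_traces`.
#' @return data frame.
#' @export
traces_to_df <- function(traces) {
  if (nrow(traces$raw) == 0L)
    return(data.frame(roi_id = integer(0), time_ms = numeric(0),
                      raw = numeric(0), dff = numeric(0)))
  out <- data.frame(
    roi_id = rep(traces$roi_ids, each = ncol(traces$raw)),
    time_ms = rep(traces$times_ms, times = nrow(traces$raw)),
    raw = as.vector(t(traces$raw)))
  if (!is.null(traces$dff)) out$dff <- as.vector(t(traces$dff))
  out
}
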