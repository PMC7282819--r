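#' Fluorescence movie container
#'
#' A `glu_movie` holds a time-ordered stack of 2-D intensity frames together
#' with the acquisition metadata needed by every downstream stage: the frame
#' interval and, for stimulated recordings, the time of the field stimulus.
#'
#' @param frames numeric 3-D array, `time x height x width`; all values must
#'   be non-negative and at least two frames are required.
#' @param frame_interval_ms positive frame interval in milliseconds.
#' @param stimulus_time_ms time of the field stimulus in ms from the start of
#'   the recording, or `NULL` for spontaneous (unstimulated) movies. Must lie
#'   within the recording when given.
#' @param pixel_size_um optional pixel size in micrometres.
#'
#' @return An object of class `glu_movie`: a list with elements `frames`,
#'   `frame_interval_ms`, `stimulus_time_ms`, `pixel_size_um`.
#' @export
glu_movie <- function(frames, frame_interval_ms, stimulus_time_ms = NULL,
                      pixel_size_um = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array (time x height x width)")
  if (dim(frames)[1] < 2L)
    stop("a movie needs at least 2 frames")
  if (any(!is.finite(frames)) || any(frames < 0))
    stop("frame intensities must be finite and non-negative")
  if (!is.numeric(frame_interval_ms) || length(frame_interval_ms) != 1L ||
      frame_interval_ms <= 0)
    stop("`frame_interval_ms` must be a single positive number")
  if (!is.null(stimulus_time_ms)) {
    if (!is.numeric(stimulus_time_ms) || length(stimulus_time_ms) != 1L ||
        stimulus_time_ms < 0)
      stop("`stimulus_time_ms` must be a single non-negative number")
    if (stimulus_time_ms >= dim(frames)[1] * frame_interval_ms)
      stop("`stimulus_time_ms` must fall within the recording")
  }
  if (!is.null(pixel_size_um) && (!is.numeric(pixel_size_um) || pixel_size_um <= 0))
    stop("`pixel_size_um` must be a positive number")
  structure(
    list(frames = frames,
         frame_interval_ms = frame_interval_ms,
         stimulus_time_ms = stimulus_time_ms,
         pixel_size_um = pixel_size_um),
    class = "glu_movie")
}

#' @export
print.glu_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<glu_movie> %d frames of %d x %d px, %g ms/frame (%.3g s total)\n",
              d[1], d[2], d[3], x$frame_interval_ms,
              d[1] * x$frame_interval_ms / 1000))
  if (!is.null(x$stimulus_time_ms))
    cat(sprintf("  field stimulus at %g ms\n", x$stimulus_time_ms))
  else
    cat("  no stimulus (spontaneous recording)\n")
  invisible(x)
}

#' @export
dim.glu_movie <- function(x) dim(x$frames)

#' Number of frames in a movie
#' @param movie a [glu_movie()].
#' @return integer frame count.
#' @export
n_frames <- function(movie) dim(movie$frames)[1]

#' Frame-center times of a movie
#'
#' Times are reported at the center of each exposure window, in ms from the
#' start of the recording (frame k covers `[(k-1)*dt, k*dt)`).
#'
#' @param movie a [glu_movie()].
#' @return numeric vector of frame-center times in ms.
#' @export
frame_times <- function(movie) {
  dt <- movie$frame_interval_ms
  (seq_len(n_frames(movie)) - 0.5) * dt
}

#' Write a movie as a multi-page 16-bit grayscale TIFF
#'
#' Intensities are multiplied by `gain`, rounded to integer counts, clipped to
#' the 16-bit range and written one page per frame. Round-tripping through
#' [read_movie_tiff()] with the same gain returns an identical array whenever
#' the scaled input is already integer-valued and in range.
#'
#' @param movie a [glu_movie()].
#' @param path output file path.
#' @param gain multiplicative gain applied before quantization (default 1,
#'   i.e. intensities are stored as counts).
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, gain = 1) {
  frames <- movie$frames * gain
  if (any(frames > 65535))
    warning("intensities exceed the 16-bit range and will be clipped")
  pages <- lapply(seq_len(dim(frames)[1]), function(t) {
    m <- round(frames[t, , , drop = TRUE])
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page grayscale TIFF as a movie
#'
#' @param path TIFF file path.
#' @param frame_interval_ms frame interval in ms (acquisition metadata; not
#'   stored in plain TIFF).
#' @param stimulus_time_ms optional stimulus time in ms.
#' @param gain gain used when the file was written; intensities are divided
#'   by it after reading.
#' @return a [glu_movie()].
#' @export
read_movie_tiff <- function(path, frame_interval_ms, stimulus_time_ms = NULL,
                            gain = 1) {
  if (!file.exists(path)) stop("cannot read TIFF: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("movie TIFF must contain at least 2 frames: ", path)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  frames <- array(0, dim = c(length(pages), h, w))
  for (t in seq_along(pages)) frames[t, , ] <- round(pages[[t]] * 65535) / gain
  glu_movie(frames, frame_interval_ms, stimulus_time_ms)
}

#' Write a single 2-D image as a 16-bit grayscale TIFF
#' @param image numeric matrix of non-negative intensities.
#' @param path output path.
#' @param gain gain applied before quantization.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, gain = 1) {
  m <- round(image * gain)
  m[m < 0] <- 0; m[m > 65535] <- 65535
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a single-plane grayscale TIFF as a matrix of counts
#' @param path TIFF path.
#' @param gain gain used at write time.
#' @return numeric matrix.
#' @export
read_image_tiff <- function(path, gain = 1) {
  if (!file.exists(path)) stop("cannot read TIFF: file not found: ", path)
  p <- tiff::readTIFF(path)
  if (length(dim(p)) == 3L) p <- p[, , 1]
  round(p * 65535) / gain
}

# --- flat key/value config files -------------------------------------------

#' Write a flat key/value configuration file
#'
#' One `key = value` pair per line; vectors are comma-separated. Every
#' pipeline run echoes its effective configuration with this format next to
#' its outputs so that any output directory is reproducible from the file.
#'
#' @param config named list of scalar or vector parameters.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    if (is.null(v)) v <- "NULL"
    paste0(k, " = ", paste(format(v, digits = 15, trim = TRUE), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key/value configuration file
#'
#' Inverse of [write_config()]: numeric-looking values are converted back to
#' numbers, `"NULL"` to `NULL`, `"TRUE"/"FALSE"` to logicals.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line (missing '='): ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    if (length(parts) == 1L && parts == "NULL") {
      out[key] <- list(NULL)
    } else if (all(parts %in% c("TRUE", "FALSE"))) {
      out[[key]] <- as.logical(parts)
    } else if (all(grepl("^[-+]?[0-9.eE+]+$", parts)) &&
               !anyNA(suppressWarnings(as.numeric(parts)))) {
      out[[key]] <- as.numeric(parts)
    } else {
      out[[key]] <- parts
    }
  }
  out
}

# Run a block of code with a locally seeded RNG, restoring the caller's RNG
# state afterwards so generators are pure functions of (config, seed).
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
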