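# Pipeline driver: each subcommand reads standard-format inputs, runs the
# corresponding analysis modules, and writes CSV/TIFF/JSON/PNG outputs plus
# a machine-readable echo of its full effective configuration, so any output
# directory is reproducible from the embedded config and seed.

.write_run_log <- function(out_dir, subcommand, config, extra = list()) {
  log <- c(list(subcommand = subcommand,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                package_version = as.character(utils::packageVersion("gluquant")),
                config = config), extra)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
}

.echo_config <- function(out_dir, config) {
  flat <- config[!vapply(config, is.list, logical(1))]
  write_config(flat, file.path(out_dir, "config.txt"))
}

.csv <- function(df, path) utils::write.csv(df, path, row.names = FALSE)

#' Run a pipeline subcommand
#'
#' Subcommands: `"simulate"` (synthetic movie + ground truth),
#' `"detect-evoked"` (ROI detection, traces, peaks, latency histogram,
#' synchronous-fraction summary), `"detect-spontaneous"` (walking-average
#' mGT detection, rates, background separation), `"fit-kinetics"`
#' (exponential fit of a time/value CSV), `"coloc"` (Costes-thresholded
#' PCC of two TIFFs), `"render"` (time-projection PNG). Every run writes
#' its outputs, a `run_log.json` and a flat `config.txt` into `out_dir`.
#'
#' @param subcommand one of the names above.
#' @param config named list of parameters for the subcommand (see the
#'   individual module functions for semantics); unknown keys error.
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(subcommand = c("simulate", "detect-evoked",
                                        "detect-spontaneous", "fit-kinetics",
                                        "coloc", "render"),
                         config = list(), out_dir) {
  subcommand <- match.arg(subcommand)
  if (missing(out_dir)) stop("`out_dir` is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(subcommand,
         "simulate" = .cmd_simulate(config, out_dir),
         "detect-evoked" = .cmd_detect_evoked(config, out_dir),
         "detect-spontaneous" = .cmd_detect_spontaneous(config, out_dir),
         "fit-kinetics" = .cmd_fit_kinetics(config, out_dir),
         "coloc" = .cmd_coloc(config, out_dir),
         "render" = .cmd_render(config, out_dir))
  invisible(out_dir)
}

.take <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

.cmd_simulate <- function(config, out_dir) {
  mode <- .take(config, "mode", "evoked")
  known <- names(formals(sim_config))
  cfg_args <- config[names(config) %in% known]
  cfg_args$mode <- mode
  cfg <- do.call(sim_config, cfg_args)
  sim <- if (mode == "evoked") simulate_evoked_movie(cfg) else
    simulate_spontaneous_movie(cfg)
  write_movie_tiff(sim$movie, file.path(out_dir, "movie.tif"))
  .csv(sim$events, file.path(out_dir, "ground_truth.csv"))
  .csv(data.frame(bouton_id = seq_len(nrow(sim$boutons)),
                  center_row = sim$boutons[, "row"],
                  center_col = sim$boutons[, "col"]),
       file.path(out_dir, "boutons.csv"))
  .echo_config(out_dir, unclass(cfg))
  .write_run_log(out_dir, "simulate", unclass(cfg),
                 list(n_events = nrow(sim$events)))
}

.read_input_movie <- function(config, default_dt, default_stim) {
  path <- config[["input"]]
  if (is.null(path)) stop("`input` (a movie TIFF path) is required")
  read_movie_tiff(path,
                  frame_interval_ms = .take(config, "frame_interval_ms", default_dt),
                  stimulus_time_ms = .take(config, "stimulus_time_ms", default_stim))
}

.cmd_detect_evoked <- function(config, out_dir) {
  movie <- .read_input_movie(config, 10, 500)
  params <- list(
    baseline_frame_count = .take(config, "baseline_frame_count", 45L),
    bandpass_radius_px = .take(config, "bandpass_radius_px", 10L),
    threshold_method = .take(config, "threshold_method", "isodata"),
    manual_value = config[["manual_value"]],
    min_area_px = .take(config, "min_area_px", 10L),
    exclude_edges = .take(config, "exclude_edges", TRUE))
  rois <- do.call(detect_rois, c(list(movie = movie), params))
  traces <- normalize_dff(extract_traces(movie, rois),
                          params$baseline_frame_count)
  peaks <- detect_peaks(traces)
  hist <- bin_peak_times(peaks,
                         t_start_ms = -movie$stimulus_time_ms,
                         t_end_ms = n_frames(movie) * movie$frame_interval_ms -
                           movie$stimulus_time_ms)
  sf <- if (nrow(peaks)) suppressWarnings(synchronous_fraction(peaks)) else NA_real_
  .csv(rois$rois, file.path(out_dir, "rois.csv"))
  write_image_tiff(rois$label_image, file.path(out_dir, "label_image.tif"))
  .csv(traces_to_df(traces), file.path(out_dir, "traces.csv"))
  .csv(peaks, file.path(out_dir, "peaks.csv"))
  .csv(data.frame(bin_start_ms = hist$bin_edges_ms[-length(hist$bin_edges_ms)],
                  bin_end_ms = hist$bin_edges_ms[-1], count = hist$counts),
       file.path(out_dir, "histogram.csv"))
  .csv(data.frame(n_rois = nrow(rois$rois), n_peaks = nrow(peaks),
                  synchronous_fraction = sf,
                  threshold = attr(rois, "threshold")),
       file.path(out_dir, "summary.csv"))
  cfg <- c(list(input = config[["input"]],
                frame_interval_ms = movie$frame_interval_ms,
                stimulus_time_ms = movie$stimulus_time_ms), params)
  cfg$manual_value <- .take(cfg, "manual_value", NA)
  .echo_config(out_dir, cfg)
  .write_run_log(out_dir, "detect-evoked", cfg,
                 list(threshold = attr(rois, "threshold"),
                      n_rois = nrow(rois$rois),
                      synchronous_fraction = sf))
}

.cmd_detect_spontaneous <- function(config, out_dir) {
  movie <- .read_input_movie(config, 200, NULL)
  params <- list(window_frames = .take(config, "window_frames", 4L),
                 spot_sigma_px = .take(config, "spot_sigma_px", 1.5),
                 snr_threshold = .take(config, "snr_threshold", 4),
                 offset_px = .take(config, "offset_px", 8),
                 n_boutons = config[["n_boutons"]])
  dm <- walking_average_subtract(movie, params$window_frames)
  events <- detect_mgt_events(dm, spot_sigma_px = params$spot_sigma_px,
                              snr_threshold = params$snr_threshold)
  sep <- suppressWarnings(
    background_roi_validation(events, dm, offset_px = params$offset_px,
                              spot_sigma_px = params$spot_sigma_px))
  dur <- diff_movie_duration_s(dm)
  rates <- data.frame(n_events = nrow(events), duration_s = dur,
                      rate_per_fov_per_min = event_rate(events, dur))
  if (!is.null(params$n_boutons))
    rates$rate_per_bouton_per_min <-
      event_rate(events, dur, "per_bouton_per_min", params$n_boutons)
  .csv(as.data.frame(events), file.path(out_dir, "events.csv"))
  .csv(rates, file.path(out_dir, "rates.csv"))
  .csv(as.data.frame(sep), file.path(out_dir, "separation.csv"))
  cfg <- c(list(input = config[["input"]],
                frame_interval_ms = movie$frame_interval_ms), params)
  cfg$n_boutons <- .take(cfg, "n_boutons", NA)
  .echo_config(out_dir, cfg)
  .write_run_log(out_dir, "detect-spontaneous", cfg,
                 list(n_events = nrow(events),
                      separation = attr(sep, "separation")))
}

.cmd_fit_kinetics <- function(config, out_dir) {
  path <- config[["input"]]
  if (is.null(path)) stop("`input` (a time/value CSV path) is required")
  if (!file.exists(path)) stop("kinetics CSV not found: ", path)
  tab <- utils::read.csv(path)
  if (!all(c("time", "value") %in% names(tab)))
    stop("kinetics CSV ", path, " must have columns `time` and `value`")
  fit <- fit_single_exponential(
    tab, fix_plateau_to_zero = .take(config, "fix_plateau_to_zero", FALSE))
  out <- data.frame(amplitude = fit$amplitude, plateau = fit$plateau,
                    tau = fit$tau, t_half = fit$t_half,
                    r_squared = fit$r_squared, sigma = fit$sigma)
  .csv(out, file.path(out_dir, "fit.csv"))
  .csv(data.frame(time = fit$data$time, value = fit$data$value,
                  fitted = fit$fitted, residual = fit$residuals),
       file.path(out_dir, "residuals.csv"))
  cfg <- list(input = path,
              fix_plateau_to_zero = .take(config, "fix_plateau_to_zero", FALSE))
  .echo_config(out_dir, cfg)
  .write_run_log(out_dir, "fit-kinetics", cfg, list(fit = as.list(out)))
}

.cmd_coloc <- function(config, out_dir) {
  p1 <- config[["input"]]; p2 <- config[["input2"]]
  if (is.null(p1) || is.null(p2))
    stop("`input` and `input2` (two single-plane TIFFs) are required")
  ch1 <- read_image_tiff(p1); ch2 <- read_image_tiff(p2)
  if (!all(dim(ch1) == dim(ch2)))
    stop("channel images differ in shape: ", p1, " vs ", p2)
  n_rect <- .take(config, "n_rect", 0L)
  if (n_rect > 0) {
    res <- coloc_rectangles(ch1, ch2, n_rect = n_rect,
                            rect_size = .take(config, "rect_size", 64L),
                            seed = .take(config, "seed", 1L))
    .csv(res$per_rectangle, file.path(out_dir, "coloc_rectangles.csv"))
    cl <- res$pooled
  } else {
    cl <- suppressWarnings(pcc_costes(ch1, ch2))
  }
  .csv(data.frame(pcc_global = cl$pcc_global,
                  costes_t1 = cl$costes_thresholds[1],
                  costes_t2 = cl$costes_thresholds[2],
                  pcc_above_threshold = cl$pcc_above_threshold,
                  n_pixels_used = cl$n_pixels_used,
                  unreliable = cl$unreliable),
       file.path(out_dir, "coloc.csv"))
  cfg <- list(input = p1, input2 = p2, n_rect = n_rect,
              seed = .take(config, "seed", 1L))
  .echo_config(out_dir, cfg)
  .write_run_log(out_dir, "coloc", cfg,
                 list(pcc_global = cl$pcc_global,
                      pcc_above_threshold = cl$pcc_above_threshold))
}

.cmd_render <- function(config, out_dir) {
  preset <- .take(config, "preset", "evoked")
  if (preset == "evoked") {
    movie <- .read_input_movie(config, 10, 500)
    t0 <- .take(config, "t_start_ms", movie$stimulus_time_ms)
    t1 <- .take(config, "t_end_ms", movie$stimulus_time_ms + 100)
    nb <- .take(config, "baseline_frame_count", 45L)
  } else {
    movie <- .read_input_movie(config, 200, NULL)
    t0 <- .take(config, "t_start_ms", 0)
    t1 <- .take(config, "t_end_ms", n_frames(movie) * movie$frame_interval_ms)
    nb <- .take(config, "baseline_frame_count",
                min(10L, n_frames(movie) - 1L))
  }
  img <- time_projection(movie, t0, t1, baseline_frame_count = nb,
                         noise_floor = config[["noise_floor"]])
  png::writePNG(img, file.path(out_dir, "time_projection.png"))
  cfg <- list(input = config[["input"]], preset = preset, t_start_ms = t0,
              t_end_ms = t1, baseline_frame_count = nb,
              noise_floor = attr(img, "noise_floor"))
  .echo_config(out_dir, cfg)
  .write_run_log(out_dir, "render", cfg)
}
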