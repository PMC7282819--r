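# Synthetic-data generators: fluorescence movies, decay time courses and
# two-channel images with known ground truth, emulating the three experiment
# classes the analysis modules consume (stimulated iGluSnFR movies, TTX
# spontaneous movies, immunoblot decay tables, two-channel ICC images).

.SYNC_WINDOW_MS <- 10  # synchronous = peak/event within 10 ms of the stimulus

#' Classify a post-stimulus latency by the 10 ms rule
#'
#' Synchronous release peaks within 10 ms of the stimulus (closed boundary);
#' later peaks are asynchronous; negative latencies fall before the stimulus.
#' The same rule is applied to simulator ground truth and to detected peaks
#' so the two are always comparable.
#'
#' @param delta_ms latency relative to the stimulus in ms (vectorised).
#' @param prestim label used for negative latencies (`"prestimulus"` for
#'   detected peaks, `"spontaneous"` for simulated background events).
#' @return character vector of class labels.
#' @export
latency_class <- function(delta_ms, prestim = "prestimulus") {
  ifelse(delta_ms < 0, prestim,
         ifelse(delta_ms <= .SYNC_WINDOW_MS, "synchronous", "asynchronous"))
}

#' Simulation configuration
#'
#' Builds a validated configuration for the movie simulators. The two modes
#' mirror the acquisition protocols of the study design being emulated:
#' evoked movies are 150 frames at 10 ms/frame with a single field stimulus
#' 500 ms after the first frame; spontaneous movies are 300 frames at
#' 200 ms/frame with no stimulus. Baseline counts scale with the exposure
#' (identical photon flux) while the Gaussian read noise does not.
#'
#' @param mode `"evoked"` or `"spontaneous"`; selects protocol defaults.
#' @param image_shape height/width in pixels.
#' @param n_boutons number of release sites.
#' @param bouton_sigma_px Gaussian point-spread sigma of a release site (px).
#' @param baseline_intensity resting fluorescence per frame, in counts.
#' @param release_probability per-bouton probability of evoked release.
#' @param sync_fraction probability that a released event draws its latency
#'   from the synchronous component.
#' @param sync_latency_mean_ms,sync_latency_sd_ms truncated-Gaussian latency
#'   of the synchronous component (truncated at 0).
#' @param async_latency_tau_ms mean of the exponential asynchronous latency.
#' @param spontaneous_rate_per_bouton_per_min homogeneous Poisson rate of
#'   background (spontaneous) release per bouton.
#' @param transient_amplitude_dff peak dF/F0 of a single release event.
#' @param transient_rise_ms,transient_decay_ms kernel time constants of the
#'   effective optical transient (see [transient_kernel()]).
#' @param noise_sd per-pixel per-frame Gaussian noise sd, in counts.
#' @param noise_model `"gaussian"` (sd independent of intensity, default) or
#'   `"scaled"` (sd grows as sqrt(intensity/baseline), a shot-noise-like
#'   variant).
#' @param bleach_tau_ms optional mono-exponential bleaching time constant.
#' @param n_frames,frame_interval_ms,stimulus_time_ms protocol timing;
#'   defaults set by `mode`.
#' @param seed integer RNG seed; generators are pure functions of
#'   (config, seed).
#' @return a named list of class `sim_config`.
#' @export
sim_config <- function(mode = c("evoked", "spontaneous"),
                       image_shape = c(128L, 128L),
                       n_boutons = 64L,
                       bouton_sigma_px = 2,
                       baseline_intensity = NULL,
                       release_probability = 0.9,
                       sync_fraction = 0.9,
                       sync_latency_mean_ms = 1.5,
                       sync_latency_sd_ms = 0.5,
                       async_latency_tau_ms = 100,
                       spontaneous_rate_per_bouton_per_min = NULL,
                       transient_amplitude_dff = NULL,
                       transient_rise_ms = 1,
                       transient_decay_ms = 15,
                       noise_sd = 20,
                       noise_model = c("gaussian", "scaled"),
                       bleach_tau_ms = NULL,
                       n_frames = NULL,
                       frame_interval_ms = NULL,
                       stimulus_time_ms = NULL,
                       seed = 1L) {
  mode <- match.arg(mode)
  noise_model <- match.arg(noise_model)
  if (mode == "evoked") {
    if (is.null(n_frames)) n_frames <- 150L
    if (is.null(frame_interval_ms)) frame_interval_ms <- 10
    if (is.null(stimulus_time_ms)) stimulus_time_ms <- 500
    if (is.null(baseline_intensity)) baseline_intensity <- 200
    if (is.null(transient_amplitude_dff)) transient_amplitude_dff <- 0.8
    if (is.null(spontaneous_rate_per_bouton_per_min))
      spontaneous_rate_per_bouton_per_min <- 0
  } else {
    if (is.null(n_frames)) n_frames <- 300L
    if (is.null(frame_interval_ms)) frame_interval_ms <- 200
    if (!is.null(stimulus_time_ms))
      stop("spontaneous configurations have no stimulus")
    if (is.null(baseline_intensity)) baseline_intensity <- 4000
    if (is.null(transient_amplitude_dff)) transient_amplitude_dff <- 0.05
    if (is.null(spontaneous_rate_per_bouton_per_min))
      spontaneous_rate_per_bouton_per_min <- 1
  }
  cfg <- list(mode = mode,
              image_shape = as.integer(image_shape),
              n_boutons = as.integer(n_boutons),
              bouton_sigma_px = bouton_sigma_px,
              baseline_intensity = baseline_intensity,
              release_probability = release_probability,
              sync_fraction = sync_fraction,
              sync_latency_mean_ms = sync_latency_mean_ms,
              sync_latency_sd_ms = sync_latency_sd_ms,
              async_latency_tau_ms = async_latency_tau_ms,
              spontaneous_rate_per_bouton_per_min = spontaneous_rate_per_bouton_per_min,
              transient_amplitude_dff = transient_amplitude_dff,
              transient_rise_ms = transient_rise_ms,
              transient_decay_ms = transient_decay_ms,
              noise_sd = noise_sd,
              noise_model = noise_model,
              bleach_tau_ms = bleach_tau_ms,
              n_frames = as.integer(n_frames),
              frame_interval_ms = frame_interval_ms,
              stimulus_time_ms = stimulus_time_ms,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$image_shape) == 2L)
  if (any(cfg$image_shape < 8L)) stop("image_shape too small")
  if (cfg$n_boutons < 1L) stop("n_boutons must be positive")
  pos <- c("bouton_sigma_px", "baseline_intensity", "sync_latency_mean_ms",
           "sync_latency_sd_ms", "async_latency_tau_ms",
           "transient_amplitude_dff", "transient_rise_ms",
           "transient_decay_ms", "frame_interval_ms")
  for (p in pos)
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0)
      stop("`", p, "` must be a positive number")
  for (p in c("release_probability", "sync_fraction"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("`", p, "` must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (cfg$spontaneous_rate_per_bouton_per_min < 0)
    stop("spontaneous rate must be non-negative")
  if (!is.null(cfg$bleach_tau_ms) && cfg$bleach_tau_ms <= 0)
    stop("`bleach_tau_ms` must be positive")
  if (cfg$n_frames < 2L) stop("need at least 2 frames")
  if (!is.null(cfg$stimulus_time_ms) &&
      cfg$stimulus_time_ms >= cfg$n_frames * cfg$frame_interval_ms)
    stop("stimulus must fall within the recording")
  invisible(cfg)
}

#' Impulse response of the optical glutamate transient
#'
#' The effective, ROI-level fluorescence response to a single release event:
#' `k(t) = (1 - exp(-t/rise)) * exp(-t/decay)`, normalized so that its
#' maximum over t equals 1 (the analytic argmax is
#' `t* = rise * log(1 + decay/rise)`). Zero for `t < 0`.
#'
#' @param t_ms time since the release event, ms (vectorised, may be >= 0).
#' @param rise_ms,decay_ms positive time constants; `decay_ms > rise_ms`
#'   is recommended.
#' @return kernel values in `[0, 1]`.
#' @export
transient_kernel <- function(t_ms, rise_ms, decay_ms) {
  if (!is.numeric(rise_ms) || rise_ms <= 0 || !is.numeric(decay_ms) || decay_ms <= 0)
    stop("kernel time constants must be positive")
  k <- ifelse(t_ms < 0, 0,
              (1 - exp(-t_ms / rise_ms)) * exp(-t_ms / decay_ms))
  k / .kernel_norm(rise_ms, decay_ms)
}

.kernel_peak_time <- function(rise_ms, decay_ms)
  rise_ms * log(1 + decay_ms / rise_ms)

.kernel_norm <- function(rise_ms, decay_ms) {
  tp <- .kernel_peak_time(rise_ms, decay_ms)
  (1 - exp(-tp / rise_ms)) * exp(-tp / decay_ms)
}

# Antiderivative of the unnormalized kernel, valid for t >= 0.
.kernel_primitive <- function(t, rise, decay) {
  -decay * exp(-t / decay) +
    (rise * decay / (rise + decay)) * exp(-t * (1 / rise + 1 / decay))
}

# Per-frame weights of an event at time `event_ms` on the frame grid,
# normalized so the best frame equals 1. The kernel is integrated over each
# exposure window (closed form) and the profile rescaled by its maximum, so
# `transient_amplitude_dff` is, by construction, the peak-frame dF/F0 an
# ideal ROI recovers. Frame argmax (the quantity peak-timing classification
# uses) is unaffected by the rescaling.
.event_frame_weights <- function(event_ms, n_frames, dt, rise, decay) {
  starts <- (seq_len(n_frames) - 1) * dt
  a <- pmax(0, starts - event_ms)
  b <- pmax(0, starts + dt - event_ms)
  w <- (.kernel_primitive(b, rise, decay) - .kernel_primitive(a, rise, decay)) / dt
  m <- max(w)
  if (m <= 0) return(numeric(n_frames))
  w / m
}

# Rejection-sample bouton centers with minimum separation 4*sigma and an
# edge margin wide enough that detected ROIs do not touch the image border.
.place_boutons <- function(shape, n, sigma, max_tries = 1e4) {
  sep2 <- (4 * sigma)^2
  margin <- ceiling(4 * sigma) + 2
  if (shape[1] - 2 * margin < 1 || shape[2] - 2 * margin < 1)
    stop("image too small to place boutons at the separation constraint")
  rows <- numeric(n); cols <- numeric(n)
  placed <- 0L; tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n, " boutons at >=4*sigma separation in a ",
           shape[1], "x", shape[2], " image (", max_tries, " attempts)")
    r <- runif(1, margin + 1, shape[1] - margin)
    c <- runif(1, margin + 1, shape[2] - margin)
    if (placed == 0L ||
        all((rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - c)^2 >= sep2)) {
      placed <- placed + 1L
      rows[placed] <- r; cols[placed] <- c
    }
  }
  cbind(row = rows, col = cols)
}

# Additive Gaussian spot with unit peak, rendered in a 4-sigma box.
.add_spot <- function(frames, t_idx, amp_by_frame, r0, c0, sigma) {
  d <- dim(frames)
  rad <- ceiling(4 * sigma)
  rr <- max(1, round(r0) - rad):min(d[2], round(r0) + rad)
  cc <- max(1, round(c0) - rad):min(d[3], round(c0) + rad)
  g <- exp(-(outer((rr - r0)^2, (cc - c0)^2, "+")) / (2 * sigma^2))
  for (i in seq_along(t_idx)) {
    frames[t_idx[i], rr, cc] <- frames[t_idx[i], rr, cc] + amp_by_frame[i] * g
  }
  frames
}

# Shared renderer: baseline (+ optional bleaching) + events + noise.
.render_movie <- function(cfg, boutons, events) {
  nt <- cfg$n_frames; dt <- cfg$frame_interval_ms
  shape <- cfg$image_shape
  tc <- (seq_len(nt) - 0.5) * dt
  bleach <- if (is.null(cfg$bleach_tau_ms)) rep(1, nt) else exp(-tc / cfg$bleach_tau_ms)
  frames <- array(rep(cfg$baseline_intensity * bleach, shape[1] * shape[2]),
                  dim = c(nt, shape[1], shape[2]))
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      w <- .event_frame_weights(events$event_time_ms[i], nt, dt,
                                cfg$transient_rise_ms, cfg$transient_decay_ms)
      on <- which(w > 1e-6)
      if (!length(on)) next
      dF <- cfg$baseline_intensity * bleach[on] * events$amplitude_dff[i] * w[on]
      frames <- .add_spot(frames, on, dF,
                          events$center_row[i], events$center_col[i],
                          cfg$bouton_sigma_px)
    }
  }
  if (cfg$noise_sd > 0) {
    if (cfg$noise_model == "gaussian") {
      frames <- frames + array(rnorm(length(frames), 0, cfg$noise_sd), dim = dim(frames))
    } else {
      sdm <- cfg$noise_sd * sqrt(pmax(frames, 0) / cfg$baseline_intensity)
      frames <- frames + array(rnorm(length(frames), 0, 1), dim = dim(frames)) * sdm
    }
    frames[frames < 0] <- 0
  }
  frames
}

.empty_events <- function() {
  data.frame(bouton_id = integer(0), center_row = numeric(0),
             center_col = numeric(0), event_time_ms = numeric(0),
             latency_class = character(0), amplitude_dff = numeric(0),
             stringsAsFactors = FALSE)
}

#' Simulate a stimulated (evoked) iGluSnFR movie with ground truth
#'
#' Emulates the single-stimulus protocol: by default 150 frames at
#' 10 ms/frame with a field stimulus 500 ms after the first frame. Each
#' bouton releases independently with `release_probability`; released events
#' draw their latency from a truncated-Gaussian synchronous component with
#' probability `sync_fraction`, otherwise from an exponential asynchronous
#' component (resampled so the transient peaks within the recording). Ground
#' truth labels follow the 10 ms rule applied to the realized latency, so a
#' nominally "synchronous" draw that lands beyond 10 ms is labelled
#' asynchronous. Background (spontaneous-process) events, if the rate is
#' non-zero, are labelled `"spontaneous"` before the stimulus and by the
#' 10 ms rule after it.
#'
#' @param config a [sim_config()] with `mode = "evoked"`.
#' @return list with elements `movie` (a [glu_movie()]) and `events`
#'   (the ground-truth data frame: `bouton_id`, `center_row`, `center_col`,
#'   `event_time_ms`, `latency_class`, `amplitude_dff`).
#' @export
simulate_evoked_movie <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "evoked") stop("config must have mode = 'evoked'")
  validate_sim_config(config)
  with_seed(config$seed, {
    boutons <- .place_boutons(config$image_shape, config$n_boutons,
                              config$bouton_sigma_px)
    stim <- config$stimulus_time_ms
    duration <- config$n_frames * config$frame_interval_ms
    max_lat <- duration - stim - 2 * config$frame_interval_ms

    ev <- list()
    released <- runif(config$n_boutons) < config$release_probability
    for (b in which(released)) {
      if (runif(1) < config$sync_fraction) {
        lat <- -1
        while (lat < 0)
          lat <- rnorm(1, config$sync_latency_mean_ms, config$sync_latency_sd_ms)
      } else {
        lat <- Inf
        while (lat > max_lat)
          lat <- rexp(1, rate = 1 / config$async_latency_tau_ms)
      }
      ev[[length(ev) + 1L]] <- data.frame(
        bouton_id = b, center_row = as.numeric(boutons[b, "row"]),
        center_col = as.numeric(boutons[b, "col"]), event_time_ms = stim + lat,
        latency_class = latency_class(lat, prestim = "spontaneous"),
        amplitude_dff = config$transient_amplitude_dff,
        stringsAsFactors = FALSE)
    }
    # superimposed background process (off by default in evoked mode)
    rate <- config$spontaneous_rate_per_bouton_per_min
    if (rate > 0) {
      dur_min <- duration / 60000
      for (b in seq_len(config$n_boutons)) {
        k <- rpois(1, rate * dur_min)
        if (k > 0) {
          tms <- runif(k, 0, duration)
          ev[[length(ev) + 1L]] <- data.frame(
            bouton_id = b, center_row = as.numeric(boutons[b, "row"]),
            center_col = as.numeric(boutons[b, "col"]), event_time_ms = tms,
            latency_class = latency_class(tms - stim, prestim = "spontaneous"),
            amplitude_dff = config$transient_amplitude_dff,
            stringsAsFactors = FALSE)
        }
      }
    }
    events <- if (length(ev)) do.call(rbind, ev) else .empty_events()
    events <- events[order(events$bouton_id, events$event_time_ms), , drop = FALSE]
    rownames(events) <- NULL
    frames <- .render_movie(config, boutons, events)
    list(movie = glu_movie(frames, config$frame_interval_ms, stim),
         events = events, boutons = boutons)
  })
}

#' Simulate a spontaneous (TTX) iGluSnFR movie with ground truth
#'
#' Emulates the spontaneous protocol: by default 300 frames at 200 ms/frame
#' and no stimulus. Per-bouton event times follow a homogeneous Poisson
#' process at `spontaneous_rate_per_bouton_per_min`; all events are labelled
#' `"spontaneous"`.
#'
#' @param config a [sim_config()] with `mode = "spontaneous"`.
#' @return list with `movie`, `events` and `boutons` as in
#'   [simulate_evoked_movie()].
#' @export
simulate_spontaneous_movie <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "spontaneous") stop("config must have mode = 'spontaneous'")
  validate_sim_config(config)
  with_seed(config$seed, {
    boutons <- .place_boutons(config$image_shape, config$n_boutons,
                              config$bouton_sigma_px)
    duration <- config$n_frames * config$frame_interval_ms
    dur_min <- duration / 60000
    rate <- config$spontaneous_rate_per_bouton_per_min
    ev <- list()
    if (rate > 0) {
      for (b in seq_len(config$n_boutons)) {
        k <- rpois(1, rate * dur_min)
        if (k > 0) {
          ev[[length(ev) + 1L]] <- data.frame(
            bouton_id = b, center_row = as.numeric(boutons[b, "row"]),
            center_col = as.numeric(boutons[b, "col"]),
            event_time_ms = sort(runif(k, 0, duration)),
            latency_class = "spontaneous",
            amplitude_dff = config$transient_amplitude_dff,
            stringsAsFactors = FALSE)
        }
      }
    }
    events <- if (length(ev)) do.call(rbind, ev) else .empty_events()
    rownames(events) <- NULL
    frames <- .render_movie(config, boutons, events)
    list(movie = glu_movie(frames, config$frame_interval_ms, NULL),
         events = events, boutons = boutons)
  })
}

#' Simulate a single-exponential decay time course
#'
#' `value(t) = plateau + (amplitude - plateau) * exp(-t/tau)` plus Gaussian
#' noise — the model used for cleavage/turnover band-intensity tables.
#'
#' @param tau positive time constant (same units as `times`).
#' @param amplitude value at `t = 0`.
#' @param plateau asymptotic value.
#' @param times strictly increasing non-negative sample times.
#' @param noise_sd Gaussian noise sd (0 for a noiseless curve).
#' @param seed RNG seed.
#' @return data frame with columns `time`, `value`.
#' @export
simulate_decay_series <- function(tau, amplitude, plateau, times,
                                  noise_sd = 0, seed = 1L) {
  if (!is.numeric(tau) || tau <= 0) stop("`tau` must be positive")
  if (!length(times) || any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop("`times` must be non-empty, strictly increasing and >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  with_seed(seed, {
    v <- plateau + (amplitude - plateau) * exp(-times / tau)
    if (noise_sd > 0) v <- v + rnorm(length(times), 0, noise_sd)
    data.frame(time = times, value = v)
  })
}

#' Simulate a two-channel image pair for colocalization analysis
#'
#' Channel 1 carries all `n_spots` Gaussian spots; channel 2 carries the
#' colocalized subset at identical centers plus
#' `(1 - colocalized_fraction) * n_spots` independently placed spots, so the
#' true colocalized fraction is known. Channels receive independent Gaussian
#' noise; channel 2 intensities are scaled by `ch2_gain` (colocalization
#' statistics must be invariant to such affine gains).
#'
#' @param image_shape height/width in pixels.
#' @param n_spots number of spots in channel 1 (>= 1).
#' @param colocalized_fraction fraction of channel-1 spots replicated at the
#'   same centers in channel 2, in `[0, 1]`.
#' @param noise_sd per-pixel Gaussian noise sd.
#' @param seed RNG seed.
#' @param spot_sigma_px Gaussian spot sigma.
#' @param spot_amplitude peak intensity of a spot, counts.
#' @param ch2_gain multiplicative gain of channel 2.
#' @return list with matrices `ch1`, `ch2` and a `truth` data frame
#'   (`spot_id`, `row`, `col`, `colocalized`).
#' @export
simulate_two_channel <- function(image_shape, n_spots, colocalized_fraction,
                                 noise_sd = 2, seed = 1L, spot_sigma_px = 2,
                                 spot_amplitude = 150, ch2_gain = 0.8) {
  if (n_spots < 1L) stop("`n_spots` must be >= 1")
  if (colocalized_fraction < 0 || colocalized_fraction > 1)
    stop("`colocalized_fraction` must lie in [0, 1]")
  with_seed(seed, {
    h <- image_shape[1]; w <- image_shape[2]
    margin <- ceiling(3 * spot_sigma_px)
    draw <- function(n) cbind(runif(n, margin + 1, h - margin),
                              runif(n, margin + 1, w - margin))
    p1 <- draw(n_spots)
    n_co <- round(colocalized_fraction * n_spots)
    extra <- draw(n_spots - n_co)

    paint <- function(centers, amp) {
      img <- array(0, dim = c(1L, h, w))
      if (nrow(centers) > 0)
        for (i in seq_len(nrow(centers)))
          img <- .add_spot(img, 1L, amp, centers[i, 1], centers[i, 2], spot_sigma_px)
      img[1, , ]
    }
    ch1 <- paint(p1, spot_amplitude)
    ch2 <- paint(rbind(p1[seq_len(n_co), , drop = FALSE], extra),
                 spot_amplitude) * ch2_gain
    if (noise_sd > 0) {
      ch1 <- ch1 + matrix(rnorm(h * w, 0, noise_sd), h, w)
      ch2 <- ch2 + matrix(rnorm(h * w, 0, noise_sd), h, w)
    }
    truth <- data.frame(
      spot_id = seq_len(n_spots + nrow(extra)),
      row = c(p1[, 1], extra[, 1]),
      col = c(p1[, 2], extra[, 2]),
      channel = c(ifelse(seq_len(n_spots) <= n_co, "both", "ch1"),
                  rep("ch2", nrow(extra))),
      colocalized = c(seq_len(n_spots) <= n_co, rep(FALSE, nrow(extra))))
    list(ch1 = ch1, ch2 = ch2, truth = truth)
  })
}
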