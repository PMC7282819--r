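# Walking-average subtraction and miniature-transient detection.

test_that("walking-average subtraction matches a running-mean oracle", {
  cm <- make_movie(replicate(20, matrix(50, 8, 8), simplify = FALSE), dt = 200)
  dm <- walking_average_subtract(cm, 4)
  expect_true(all(abs(dm$frames) < 1e-12))
  expect_equal(dim(dm$frames)[1], 17)

  # length 300 with window 4 loses exactly three leading frames
  long <- glu_movie(array(5, dim = c(300, 4, 4)), 200)
  expect_equal(dim(walking_average_subtract(long, 4)$frames)[1], 297)

  # step movie: 0 then a from frame s; amplitude a*(w-1)/w at the step
  a <- 12; s <- 10; w <- 4
  fl <- lapply(1:20, function(i) matrix(if (i >= s) a else 0, 6, 6))
  mv <- make_movie(fl, dt = 200)
  dm2 <- walking_average_subtract(mv, w)
  # direct running-mean oracle over the whole series
  for (t in seq_len(20 - w + 1)) {
    expected <- fl[[t + w - 1]][1, 1] - mean(vapply(t:(t + w - 1),
                                                   function(i) fl[[i]][1, 1],
                                                   numeric(1)))
    expect_equal(dm2$frames[t, 1, 1], expected, tolerance = 1e-12)
  }
  expect_equal(dm2$frames[s - w + 1, 3, 3], a * (w - 1) / w)

  expect_error(walking_average_subtract(cm, 21), "smaller")
  expect_error(walking_average_subtract(cm, 1), ">= 2")
})

# Build a spontaneous-style movie with hand-placed events.
render_spont <- function(event_times_ms, centers, amp = 0.05, noise = 20,
                         shape = c(64, 64), seed = 1) {
  cfg <- sim_config("spontaneous", image_shape = shape, n_boutons = 2,
                    transient_amplitude_dff = amp, noise_sd = noise,
                    seed = seed)
  events <- data.frame(bouton_id = seq_along(event_times_ms),
                       center_row = centers[, 1], center_col = centers[, 2],
                       event_time_ms = event_times_ms,
                       latency_class = "spontaneous", amplitude_dff = amp)
  boutons <- cbind(row = centers[, 1], col = centers[, 2])
  frames <- gluquant:::with_seed(seed,
                                 gluquant:::.render_movie(cfg, boutons, events))
  glu_movie(frames, 200)
}

test_that("a noiseless transient is found at its injected frame", {
  mv <- render_spont(20300, cbind(30, 30), noise = 0)
  ev <- detect_mgt_events(walking_average_subtract(mv, 4), spot_sigma_px = 2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$frame, 102, tolerance = 1)   # frame 102 covers 20200-20400
  expect_equal(ev$center_row, 30, tolerance = 1)
  expect_true(is.infinite(ev$snr))
})

test_that("four well-separated SNR-10 transients give exactly four events", {
  centers <- rbind(c(15, 15), c(15, 48), c(48, 15), c(48, 48))
  mv <- render_spont(c(5100, 15100, 30100, 45100), centers,
                     amp = 0.05, noise = 20, seed = 33)
  ev <- detect_mgt_events(walking_average_subtract(mv, 4), spot_sigma_px = 2)
  expect_equal(nrow(ev), 4)
  expect_true(all(ev$snr >= 4))
})

test_that("detection is silent on pure noise at the default threshold", {
  fp <- 0L
  for (s in 1:10) {
    cfg <- sim_config("spontaneous", image_shape = c(64, 64), n_boutons = 2,
                      spontaneous_rate_per_bouton_per_min = 0, seed = 600L + s)
    mv <- simulate_spontaneous_movie(cfg)$movie
    fp <- fp + nrow(detect_mgt_events(walking_average_subtract(mv, 4),
                                      spot_sigma_px = 2))
  }
  expect_lte(fp, 1L)
})

test_that("detection ignores a spatially uniform offset", {
  mv <- render_spont(c(5100, 30100), rbind(c(20, 20), c(44, 44)), seed = 9)
  ev1 <- detect_mgt_events(walking_average_subtract(mv, 4), spot_sigma_px = 2)
  shifted <- glu_movie(mv$frames + 500, mv$frame_interval_ms)
  ev2 <- detect_mgt_events(walking_average_subtract(shifted, 4),
                           spot_sigma_px = 2)
  expect_equal(as.data.frame(ev1), as.data.frame(ev2), tolerance = 1e-9)
})

test_that("background ROIs separate cleanly from events", {
  centers <- rbind(c(16, 16), c(16, 46), c(46, 16), c(46, 46))
  mv <- render_spont(c(8100, 20100, 35100, 50100), centers, seed = 21)
  dm <- walking_average_subtract(mv, 4)
  ev <- detect_mgt_events(dm, spot_sigma_px = 2)
  expect_gte(nrow(ev), 3)

  sep <- background_roi_validation(ev, dm, offset_px = c(12, 0),
                                   spot_sigma_px = 2)
  expect_gt(attr(sep, "separation"), 0)
  expect_true(all(sep$snr > sep$bg_snr))

  # zero offset reproduces the event measurements exactly
  sep0 <- background_roi_validation(ev, dm, offset_px = 0, spot_sigma_px = 2)
  expect_equal(sep0$bg_peak_df, sep0$peak_df, tolerance = 1e-9)
  expect_equal(sep0$bg_snr, sep0$snr, tolerance = 1e-9)

  # an offset pushing ROIs outside the image is skipped with a warning
  expect_warning(background_roi_validation(ev, dm, offset_px = c(100, 0),
                                           spot_sigma_px = 2), "skipped")
})

test_that("background amplitudes scatter symmetrically around zero", {
  # many background measurements via zero events + direct sampling
  cfg <- sim_config("spontaneous", image_shape = c(64, 64), n_boutons = 2,
                    spontaneous_rate_per_bouton_per_min = 0, seed = 77)
  dm <- walking_average_subtract(simulate_spontaneous_movie(cfg)$movie, 4)
  S <- gluquant:::.smooth_frames(dm$frames, 2 / 1.5)
  set.seed(11)
  samp <- S[cbind(sample(297, 200, TRUE), sample(5:60, 200, TRUE),
                  sample(5:60, 200, TRUE))]
  se <- stats::sd(samp) / sqrt(length(samp))
  expect_lt(abs(mean(samp)), 3 * se)
})

test_that("event rates scale to the requested unit", {
  ev12 <- data.frame(event_id = 1:12)
  expect_equal(event_rate(ev12, 60), 12)
  expect_equal(event_rate(ev12, 60, "per_bouton_per_min", n_boutons = 4), 3)
  expect_equal(event_rate(ev12[0, , drop = FALSE], 60), 0)
  expect_error(event_rate(ev12, 0), "positive")
  expect_error(event_rate(ev12, 60, "per_bouton_per_min"), "n_boutons")
})
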