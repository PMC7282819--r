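# Synthetic-data generators: kernel shape, ground-truth statistics,
# determinism and noise monotonicity.

test_that("transient kernel vanishes at onset and infinity and peaks at 1", {
  expect_equal(transient_kernel(0, 2, 80), 0)
  expect_lt(transient_kernel(5000, 2, 80), 1e-10)
  expect_error(transient_kernel(1, -2, 80), "positive")
  expect_error(transient_kernel(1, 2, 0), "positive")

  # dense grid-search oracle at 0.01 ms resolution for rise 2 / decay 80
  tt <- seq(0, 600, by = 0.01)
  raw <- (1 - exp(-tt / 2)) * exp(-tt / 80)
  t_star <- tt[which.max(raw)]
  expect_equal(t_star, 2 * log(1 + 80 / 2), tolerance = 0.01)
  expect_equal(transient_kernel(t_star, 2, 80), 1, tolerance = 1e-6)
  expect_true(all(transient_kernel(tt, 2, 80) <= 1 + 1e-12))

  # and for the package's default constants
  expect_equal(transient_kernel(1 * log(1 + 15), 1, 15), 1, tolerance = 1e-10)
})

test_that("deterministic evoked release yields exactly one event per bouton", {
  cfg <- sim_config("evoked", image_shape = c(64, 64), n_boutons = 8,
                    release_probability = 1, noise_sd = 0, seed = 4)
  sim <- simulate_evoked_movie(cfg)
  expect_equal(nrow(sim$events), 8)
  expect_true(all(sim$events$event_time_ms >= 500))
  # conservation: one ground-truth row per bouton, each bouton once
  expect_equal(sort(sim$events$bouton_id), 1:8)
})

test_that("silent configuration produces a constant movie", {
  cfg <- sim_config("evoked", image_shape = c(48, 48), n_boutons = 3,
                    release_probability = 0,
                    spontaneous_rate_per_bouton_per_min = 0,
                    noise_sd = 0, seed = 1)
  sim <- simulate_evoked_movie(cfg)
  expect_equal(nrow(sim$events), 0)
  f1 <- sim$movie$frames[1, , ]
  for (t in seq_len(n_frames(sim$movie)))
    expect_equal(sim$movie$frames[t, , ], f1)
  expect_true(all(f1 == cfg$baseline_intensity))
})

test_that("ground-truth latency classes follow the 10 ms rule by construction", {
  sim <- simulate_evoked_movie(sim_config("evoked", image_shape = c(64, 64),
                                          n_boutons = 10, sync_fraction = 0.5,
                                          release_probability = 1, seed = 8))
  lat <- sim$events$event_time_ms - 500
  expect_identical(sim$events$latency_class,
                   latency_class(lat, prestim = "spontaneous"))
})

test_that("realized latency mixture matches a Monte-Carlo oracle", {
  sf <- 0.8
  # pool ground truth over seeds until >= 2000 released events
  lat <- c()
  s <- 0L
  while (length(lat) < 2000) {
    s <- s + 1L
    cfg <- sim_config("evoked", image_shape = c(64, 64), n_boutons = 25,
                      bouton_sigma_px = 1, release_probability = 1,
                      sync_fraction = sf, noise_sd = 0, seed = 1000L + s)
    sim <- simulate_evoked_movie(cfg)
    lat <- c(lat, sim$events$event_time_ms - 500)
  }
  phat <- mean(lat <= 10)

  # 1e6-draw latency-mixture oracle (truncated normal / exponential)
  set.seed(99)
  n <- 1e6
  is_sync <- runif(n) < sf
  l_sync <- abs(rep(NA_real_, n))
  draw <- rnorm(n, 1.5, 0.5)
  while (any(draw < 0)) draw[draw < 0] <- rnorm(sum(draw < 0), 1.5, 0.5)
  l_async <- rexp(n, 1 / 100)
  l <- ifelse(is_sync, draw, l_async)
  p_oracle <- mean(l <= 10)

  ci_half <- 2.576 * sqrt(p_oracle * (1 - p_oracle) / length(lat))
  expect_lt(abs(phat - p_oracle), ci_half)
})

test_that("spontaneous event counts follow the Poisson mean", {
  cfg0 <- sim_config("spontaneous", image_shape = c(64, 64), n_boutons = 5,
                     spontaneous_rate_per_bouton_per_min = 0, seed = 2)
  expect_equal(nrow(simulate_spontaneous_movie(cfg0)$events), 0)

  # rate 2 / bouton / min, 50 boutons, 60 s -> mean 100 per movie
  counts <- vapply(1:100, function(s) {
    cfg <- sim_config("spontaneous", image_shape = c(96, 96), n_boutons = 50,
                      bouton_sigma_px = 1, noise_sd = 0,
                      spontaneous_rate_per_bouton_per_min = 2, seed = 3000L + s)
    nrow(simulate_spontaneous_movie(cfg)$events)
  }, numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 100), 3 * se)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config("evoked", image_shape = c(48, 48), n_boutons = 4, seed = 12)
  a <- simulate_evoked_movie(cfg)
  b <- simulate_evoked_movie(cfg)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$events, b$events)

  cfgs <- sim_config("spontaneous", image_shape = c(48, 48), n_boutons = 3,
                     seed = 12)
  a <- simulate_spontaneous_movie(cfgs)
  b <- simulate_spontaneous_movie(cfgs)
  expect_identical(a$movie$frames, b$movie$frames)

  # and the RNG state of the session is left untouched
  set.seed(77); x1 <- runif(1)
  set.seed(77); invisible(simulate_evoked_movie(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("decay series obeys its closed form", {
  d <- simulate_decay_series(41, 1, 0, times = c(0, 28.4, 410), noise_sd = 0)
  expect_equal(d$value[1], 1)
  expect_equal(d$value[2], 0.5, tolerance = 1e-3)
  expect_equal(d$value[3], 0, tolerance = 1e-4)
  d2 <- simulate_decay_series(10, 2, 0.5, times = c(0, 100), noise_sd = 0)
  expect_equal(d2$value[1], 2)
  expect_lt(abs(d2$value[2] - 0.5), 1e-4)
  expect_error(simulate_decay_series(-1, 1, 0, times = 0:3), "positive")
  expect_error(simulate_decay_series(1, 1, 0, times = c(2, 1)), "increasing")
})

test_that("two-channel simulator respects the colocalized fraction", {
  full <- simulate_two_channel(c(64, 64), 20, 1, noise_sd = 0, seed = 5)
  expect_equal(max(abs(full$ch2 - 0.8 * full$ch1)), 0, tolerance = 1e-12)
  none <- simulate_two_channel(c(64, 64), 20, 0, noise_sd = 0, seed = 5)
  expect_true(all(!none$truth$colocalized))
  expect_equal(sum(none$truth$channel == "ch2"), 20)
  # disjoint center sets: every ch2-only spot away from every ch1 spot center
  t1 <- none$truth[none$truth$channel == "ch1", ]
  t2 <- none$truth[none$truth$channel == "ch2", ]
  d <- sqrt(outer(t1$row, t2$row, "-")^2 + outer(t1$col, t2$col, "-")^2)
  expect_true(all(d > 0))
})

test_that("rendered per-event peak SNR decreases with noise level", {
  snr_at <- function(noise) {
    cfg <- sim_config("evoked", image_shape = c(64, 64), n_boutons = 6,
                      release_probability = 1, noise_sd = noise, seed = 21)
    sim <- simulate_evoked_movie(cfg)
    base <- colMeans(sim$movie$frames[1:45, , ])
    snrs <- vapply(seq_len(nrow(sim$events)), function(i) {
      r <- round(sim$events$center_row[i]); c <- round(sim$events$center_col[i])
      tr <- sim$movie$frames[, r, c]
      (max(tr) - base[r, c]) / max(stats::sd(tr[1:45]), 1e-9)
    }, numeric(1))
    mean(snrs)
  }
  s <- vapply(c(5, 15, 45), snr_at, numeric(1))
  expect_true(all(diff(s) < 0))
})

test_that("bouton placement fails gracefully when the image is too crowded", {
  expect_error(simulate_evoked_movie(
    sim_config("evoked", image_shape = c(32, 32), n_boutons = 50, seed = 1)),
    "place|small")
})
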