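# Time-projection rendering, TIFF/config round trips, pipeline subcommands.

test_that("time projection colors early events red and late events purple", {
  base <- matrix(100, 24, 24)
  fl <- replicate(60, base, simplify = FALSE)
  # early event (window start) at (6,6); late event (window end) at (18,18)
  fl[[31]][5:7, 5:7] <- 100 + 80
  fl[[58]][17:19, 17:19] <- 100 + 80
  mv <- make_movie(fl, dt = 10, stim = 300)
  img <- time_projection(mv, 300, 580, baseline_frame_count = 20)

  hue_at <- function(r, c) {
    rgb <- grDevices::rgb2hsv(img[r, c, 1], img[r, c, 2], img[r, c, 3],
                              maxColorValue = 1)
    unname(rgb["h", 1])
  }
  expect_lt(hue_at(6, 6), 0.05)                       # red
  expect_gt(hue_at(18, 18), 0.75)                     # purple
  # hue ordering matches time ordering and the closed-form ramp
  t_early <- attr(img, "peak_time_ms")[6, 6]
  expect_equal(hue_at(6, 6),
               time_ramp_hue((t_early - 300) / 280), tolerance = 1e-2)
  # quiet pixels fall below the noise floor and stay black
  expect_equal(sum(img[12, 12, ]), 0)
  expect_error(time_projection(mv, 400, 300), "window")
})

test_that("movies survive a 16-bit TIFF round trip", {
  set.seed(3)
  arr <- array(sample(0:4000, 10 * 16 * 16, TRUE), dim = c(10, 16, 16))
  mv <- glu_movie(arr, 10, 50)
  path <- tempfile(fileext = ".tif")
  write_movie_tiff(mv, path)
  back <- read_movie_tiff(path, 10, 50)
  expect_identical(back$frames, mv$frames + 0)
  expect_equal(n_frames(back), 10)
})

test_that("configs survive a key/value round trip", {
  cfg <- list(alpha = 1.5, n = 3L, name = "isodata", flag = TRUE,
              vec = c(1, 2, 3), empty = NULL)
  path <- tempfile(fileext = ".txt")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$alpha, 1.5)
  expect_equal(back$n, 3)
  expect_equal(back$name, "isodata")
  expect_true(back$flag)
  expect_equal(back$vec, c(1, 2, 3))
  expect_null(back$empty)
})

test_that("simulate + detect-evoked subcommands are reproducible end to end", {
  base_cfg <- list(mode = "evoked", image_shape = c(64, 64), n_boutons = 8,
                   seed = 6)
  d1 <- file.path(tempdir(), "run1"); d2 <- file.path(tempdir(), "run2")
  run_pipeline("simulate", base_cfg, d1)
  run_pipeline("simulate", base_cfg, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "ground_truth.csv"))),
                   unname(tools::md5sum(file.path(d2, "ground_truth.csv"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "movie.tif"))),
                   unname(tools::md5sum(file.path(d2, "movie.tif"))))

  e1 <- file.path(tempdir(), "ev1"); e2 <- file.path(tempdir(), "ev2")
  run_pipeline("detect-evoked", list(input = file.path(d1, "movie.tif")), e1)
  run_pipeline("detect-evoked", list(input = file.path(d2, "movie.tif")), e2)
  expect_identical(unname(tools::md5sum(file.path(e1, "summary.csv"))),
                   unname(tools::md5sum(file.path(e2, "summary.csv"))))
  smry <- utils::read.csv(file.path(e1, "summary.csv"))
  expect_true("synchronous_fraction" %in% names(smry))
  expect_true(smry$synchronous_fraction >= 0 && smry$synchronous_fraction <= 1)
  expect_true(file.exists(file.path(e1, "run_log.json")))
  expect_true(file.exists(file.path(e1, "config.txt")))
})

test_that("malformed inputs produce descriptive errors", {
  one <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 8, 8), one, bits.per.sample = 16L)
  expect_error(run_pipeline("detect-evoked", list(input = one),
                            file.path(tempdir(), "bad1")), "2 frames")
  expect_error(run_pipeline("detect-evoked", list(),
                            file.path(tempdir(), "bad2")), "input")
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1:3), csv, row.names = FALSE)
  expect_error(run_pipeline("fit-kinetics", list(input = csv),
                            file.path(tempdir(), "bad3")), "time")
})

test_that("kinetics, coloc and render subcommands write their outputs", {
  d <- simulate_decay_series(41, 1, 0.1, seq(0, 280, 40), noise_sd = 0.02,
                             seed = 2)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(d, csv, row.names = FALSE)
  kd <- file.path(tempdir(), "kin")
  run_pipeline("fit-kinetics", list(input = csv), kd)
  fit <- utils::read.csv(file.path(kd, "fit.csv"))
  expect_equal(fit$tau, 41, tolerance = 0.2)
  expect_equal(fit$t_half, fit$tau * log(2))

  sim <- simulate_two_channel(c(64, 64), 30, 0.8, noise_sd = 3, seed = 4)
  p1 <- tempfile(fileext = ".tif"); p2 <- tempfile(fileext = ".tif")
  write_image_tiff(sim$ch1 - min(sim$ch1), p1)
  write_image_tiff(sim$ch2 - min(sim$ch2), p2)
  cd <- file.path(tempdir(), "coloc")
  run_pipeline("coloc", list(input = p1, input2 = p2), cd)
  cl <- utils::read.csv(file.path(cd, "coloc.csv"))
  expect_gt(cl$pcc_above_threshold, 0.5)

  sd1 <- file.path(tempdir(), "simr")
  run_pipeline("simulate", list(mode = "evoked", image_shape = c(64, 64),
                                n_boutons = 8, seed = 6), sd1)
  rd <- file.path(tempdir(), "render")
  run_pipeline("render", list(input = file.path(sd1, "movie.tif"),
                              preset = "evoked"), rd)
  expect_true(file.exists(file.path(rd, "time_projection.png")))
  png_img <- png::readPNG(file.path(rd, "time_projection.png"))
  expect_equal(dim(png_img)[1:2], c(64, 64))
})
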