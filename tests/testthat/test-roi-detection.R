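# ROI segmentation: projections, band-pass, thresholding, watershed,
# particle labeling — each against an independent oracle — plus the
# end-to-end recovery and null-specificity properties.

test_that("baseline projection equals a direct per-pixel mean", {
  cm <- make_movie(replicate(10, matrix(7, 8, 8), simplify = FALSE))
  expect_true(all(baseline_projection(cm, 5) == 7))

  alt <- make_movie(lapply(1:12, function(i) matrix(c(0, 2)[(i %% 2) + 1], 8, 8)))
  expect_true(all(baseline_projection(alt, 10) == 1))

  set.seed(31)
  rnd <- make_movie(lapply(1:12, function(i) matrix(runif(64, 0, 100), 8, 8)))
  direct <- Reduce(`+`, lapply(1:6, function(t) rnd$frames[t, , ])) / 6
  expect_equal(baseline_projection(rnd, 6), direct, tolerance = 1e-6)

  expect_error(baseline_projection(cm, 0), "baseline_frame_count")
  expect_error(baseline_projection(cm, 10), "baseline_frame_count")
  stim <- make_movie(replicate(10, matrix(1, 8, 8), simplify = FALSE), stim = 30)
  expect_warning(baseline_projection(stim, 5), "stimulus")
})

test_that("response image isolates the added transient", {
  cm <- make_movie(replicate(10, matrix(3, 8, 8), simplify = FALSE))
  expect_true(all(response_image(cm, 5) == 0))

  fl <- replicate(10, matrix(3, 8, 8), simplify = FALSE)
  fl[[7]][4, 5] <- 3 + 11
  mv <- make_movie(fl)
  resp <- response_image(mv, 5)
  expect_equal(resp[4, 5], 11)
  expect_true(all(resp[-(4 + (5 - 1) * 8)] == 0))

  # synthetic evoked movie: response at ground-truth centers covers at least
  # 80% of the injected PSF peak (closed-form Gaussian rendering oracle)
  cfg <- sim_config("evoked", image_shape = c(64, 64), n_boutons = 6,
                    release_probability = 1, noise_sd = 0, seed = 14)
  sim <- simulate_evoked_movie(cfg)
  resp <- response_image(sim$movie, 45)
  for (i in seq_len(nrow(sim$events))) {
    r <- round(sim$events$center_row[i]); c <- round(sim$events$center_col[i])
    peak <- cfg$baseline_intensity * cfg$transient_amplitude_dff *
      oracle_gauss(r - sim$events$center_row[i], c - sim$events$center_col[i],
                   cfg$bouton_sigma_px)
    expect_gte(resp[r, c], 0.8 * peak)
  }
})

test_that("band-pass equals image minus circular-mean filter", {
  cm <- matrix(5, 40, 40)
  expect_true(all(abs(bandpass(cm, 10)) < 1e-12))

  # single bright pixel: neighbourhood-count oracle for the radius-10 disc
  img <- matrix(0, 60, 60); img[30, 30] <- 120
  n_nb <- sum(outer((-10:10)^2, (-10:10)^2, "+") <= 100)
  bp <- bandpass(img, 10)
  expect_equal(bp[30, 30], 120 * (1 - 1 / n_nb), tolerance = 1e-8)

  set.seed(8)
  rnd <- matrix(runif(1600, 0, 50), 40, 40)
  expect_equal(bandpass(rnd, 5) + mean_filter(rnd, 5), rnd, tolerance = 1e-9)
  expect_error(bandpass(matrix(0, 15, 15), 10), "radius")
})

test_that("isodata threshold is the histogram fixed point", {
  set.seed(41)
  bimodal <- matrix(c(rnorm(2000, 10, 1), rnorm(2000, 100, 5)), 40, 100)
  mask <- threshold_auto(bimodal, "isodata")
  thr <- attr(mask, "threshold")
  expect_gt(thr, 10); expect_lt(thr, 100)
  bin_w <- diff(range(bimodal)) / 256
  expect_lt(abs(thr - oracle_isodata(bimodal)), 2 * bin_w)

  man <- threshold_auto(matrix(c(40, 60, 40, 60), 2, 2), "manual",
                        manual_value = 50)
  expect_identical(as.vector(man), c(FALSE, TRUE, FALSE, TRUE))

  # mask size is non-increasing in the manual threshold
  counts <- vapply(c(20, 50, 80, 101),
                   function(v) sum(threshold_auto(bimodal, "manual",
                                                  manual_value = v)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(threshold_auto(matrix(1, 5, 5), "isodata"), "constant")
})

test_that("watershed splits touching discs and leaves single objects alone", {
  disc <- function(shape, r0, c0, rad) {
    m <- matrix(FALSE, shape[1], shape[2])
    for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
      if ((i - r0)^2 + (j - c0)^2 <= rad^2) m[i, j] <- TRUE
    m
  }
  single <- disc(c(30, 30), 15, 15, 6)
  expect_identical(watershed_split(single), single)

  two <- disc(c(40, 40), 20, 15, 6) | disc(c(40, 40), 20, 25, 6)
  expect_equal(max(oracle_label8(two)), 1)  # overlapping: one blob before
  split <- watershed_split(two)
  expect_equal(max(oracle_label8(split)), 2)
  # splitting never merges
  expect_gte(max(oracle_label8(split)), max(oracle_label8(two)))
  expect_false(any(watershed_split(matrix(FALSE, 10, 10))))
})

test_that("particle labeling matches a flood-fill oracle and filters apply", {
  blob <- function(m, px) { for (p in px) m[p[1], p[2]] <- TRUE; m }
  m <- matrix(FALSE, 30, 30)
  m[5:8, 5:7] <- TRUE                 # 12 px
  m[20:23, 20:22] <- TRUE             # 12 px
  rois <- label_rois(m)
  expect_equal(nrow(rois$rois), 2)
  expect_equal(rois$rois$area_px, c(12L, 12L))

  # >= 10 px convention: a 9 px blob dies, a 10 px blob survives
  m2 <- matrix(FALSE, 30, 30)
  m2[5:7, 5:7] <- TRUE                      # 9 px
  m2[20:24, 20:21] <- TRUE                  # 10 px
  r2 <- label_rois(m2)
  expect_equal(nrow(r2$rois), 1)
  expect_equal(r2$rois$area_px, 10L)

  # border exclusion removes a 30 px blob touching the top edge
  m3 <- matrix(FALSE, 30, 30)
  m3[1:5, 10:15] <- TRUE
  expect_equal(nrow(label_rois(m3)$rois), 0)
  expect_equal(nrow(label_rois(m3, exclude_edges = FALSE)$rois), 1)

  # random masks up to 64x64: labeling equals the flood-fill oracle
  for (s in 1:6) {
    set.seed(400 + s)
    rm <- matrix(runif(64 * 64) < 0.35, 64, 64)
    impl <- label_rois(rm, min_area_px = 1L, exclude_edges = FALSE)
    filled <- EBImage::fillHull(matrix(as.numeric(rm), 64, 64)) > 0
    expect_identical(canonical_components(impl$label_image),
                     canonical_components(oracle_label8(filled)))
  }
})

test_that("roi ids are contiguous and the label image partitions its pixels", {
  set.seed(17)
  rm <- matrix(runif(48 * 48) < 0.3, 48, 48)
  rois <- label_rois(rm, min_area_px = 3L)
  ids <- rois$rois$roi_id
  expect_identical(ids, seq_along(ids))
  for (k in ids)
    expect_equal(sum(rois$label_image == k), rois$rois$area_px[k])
  expect_true(all(!rois$rois$touches_edge))
})

test_that("segmentation recovers releasing boutons with high precision and recall", {
  sim <- simulate_evoked_movie(sim_config("evoked", seed = 7))
  rois <- detect_rois(sim$movie)
  releasing <- sim$boutons[unique(sim$events$bouton_id), , drop = FALSE]
  m <- match_rois(rois, releasing, max_dist_px = 3)
  expect_gte(m$precision, 0.9)
  expect_gte(m$recall, 0.9)
})

test_that("the chain stays quiet on a pure-noise movie", {
  sig <- simulate_evoked_movie(sim_config("evoked", seed = 7))
  n_sig <- nrow(detect_rois(sig$movie)$rois)
  noise <- simulate_evoked_movie(sim_config("evoked", release_probability = 0,
                                            seed = 7))
  n_noise <- nrow(detect_rois(noise$movie)$rois)
  expect_lte(n_noise, 0.02 * n_sig)
})
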