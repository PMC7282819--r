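# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (brute force, direct summation, closed forms) so
# they share no code path with the implementation they check.

# Stack-based 8-connected flood-fill labeling.
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j)); lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Canonical representation of a labeling: sorted list of sorted pixel-index
# sets, so two labelings compare equal iff they induce the same partition.
canonical_components <- function(lab) {
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  comps <- lapply(ids, function(k) sort(which(lab == k)))
  comps[order(vapply(comps, min, integer(1)))]
}

# Direct value-iteration isodata (no histogram): fixed point of the
# mean-of-means rule on the raw pixel values.
oracle_isodata <- function(x, max_iter = 1000) {
  thr <- mean(x)
  for (i in seq_len(max_iter)) {
    lo <- x <= thr
    if (!any(lo) || all(lo)) break
    new <- (mean(x[lo]) + mean(x[!lo])) / 2
    if (abs(new - thr) < 1e-10) return(new)
    thr <- new
  }
  thr
}

# Kruskal-Wallis H by the direct rank formula with tie correction.
oracle_kw_H <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Exhaustive Costes scan on an integer-valued (8-bit style) image pair:
# every integer level from max(ch1) down, with its own closed-form
# orthogonal regression.
oracle_costes <- function(ch1, ch2) {
  x <- as.numeric(ch1); y <- as.numeric(ch2)
  mx <- mean(x); my <- mean(y)
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  a <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  b <- my - a * mx
  for (T in seq(max(x), min(x), by = -1)) {
    sel <- x < T & y < a * T + b
    if (sum(sel) < 2 || stats::sd(x[sel]) == 0 || stats::sd(y[sel]) == 0) next
    if (stats::cor(x[sel], y[sel]) <= 0) return(c(T, a * T + b))
  }
  c(NA_real_, NA_real_)
}

# Closed-form Gaussian spot value at an offset from a fractional center.
oracle_gauss <- function(dr, dc, sigma) exp(-(dr^2 + dc^2) / (2 * sigma^2))

# Frame-averaged transient profile by numerical quadrature (independent of
# the closed-form primitive used by the renderer).
oracle_frame_weights <- function(event_ms, n_frames, dt, rise, decay,
                                 n_sub = 2000) {
  w <- vapply(seq_len(n_frames), function(f) {
    tt <- seq((f - 1) * dt, f * dt, length.out = n_sub)
    s <- tt - event_ms
    k <- ifelse(s < 0, 0, (1 - exp(-s / rise)) * exp(-s / decay))
    mean(k)
  }, numeric(1))
  tp <- rise * log(1 + decay / rise)
  w / ((1 - exp(-tp / rise)) * exp(-tp / decay)) # unnormalized -> kernel units
}

# A tiny deterministic movie built by hand (no simulator involvement).
make_movie <- function(frames_list, dt = 10, stim = NULL) {
  arr <- array(0, dim = c(length(frames_list), nrow(frames_list[[1]]),
                          ncol(frames_list[[1]])))
  for (i in seq_along(frames_list)) arr[i, , ] <- frames_list[[i]]
  glu_movie(arr, dt, stim)
}

# Hand-built ROI set wrapping a label matrix.
make_rois <- function(label_image) {
  ids <- setdiff(sort(unique(as.integer(label_image))), 0L)
  rois <- do.call(rbind, lapply(ids, function(k) {
    px <- which(label_image == k, arr.ind = TRUE)
    data.frame(roi_id = k, area_px = nrow(px),
               centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]),
               touches_edge = FALSE)
  }))
  structure(list(label_image = label_image, rois = rois), class = "glu_rois")
}
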