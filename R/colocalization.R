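# Two-channel colocalization: Pearson's correlation coefficient with the
# Costes automatic threshold, optionally over sampled rectangular regions.

#' Pearson's correlation coefficient between two channels
#'
#' Standard product-moment correlation over the (optionally masked) pixels.
#' A constant channel makes the correlation undefined: `NA` is returned
#' with a warning.
#'
#' @param ch1,ch2 numeric matrices of identical shape.
#' @param mask optional logical matrix selecting the pixels to use
#'   (>= 2 pixels).
#' @return correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson <- function(ch1, ch2, mask = NULL) {
  if (!all(dim(ch1) == dim(ch2))) stop("channels must have identical shape")
  x <- as.numeric(ch1); y <- as.numeric(ch2)
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(ch1))) stop("mask shape mismatch")
    x <- x[mask]; y <- y[mask]
  }
  if (length(x) < 2) stop("need at least 2 pixels")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant channel within mask; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

# Orthogonal (major-axis) regression ch2 ~ a * ch1 + b.
.orthogonal_regression <- function(x, y) {
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  a <- if (abs(sxy) < .Machine$double.eps) 0 else
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  b <- mean(y) - a * mean(x)
  c(slope = a, intercept = b)
}

#' Costes automatic threshold for a channel pair
#'
#' Channel 2 is regressed on channel 1 by orthogonal (major-axis)
#' regression, `ch2 ~ a * ch1 + b`. Candidate thresholds `T` on channel 1
#' are scanned downward from its maximum; the Costes threshold is the
#' largest `T` for which the Pearson correlation computed over the pixels
#' *below* threshold in both channels (`ch1 < T` and `ch2 < a*T + b`) drops
#' to zero or below — i.e. the point below which the channels carry no
#' residual correlation. Returns `(T, a*T + b)`. If no candidate satisfies
#' the criterion (e.g. perfectly correlated noiseless channels), both
#' thresholds fall to the channel minima with a warning.
#'
#' @param ch1,ch2 numeric matrices of identical shape.
#' @param n_levels number of candidate levels scanned (default 256).
#' @return numeric vector `c(t1, t2)` with attributes `slope`, `intercept`
#'   and `fell_to_minimum`.
#' @export
costes_threshold <- function(ch1, ch2, n_levels = 256L) {
  if (!all(dim(ch1) == dim(ch2))) stop("channels must have identical shape")
  x <- as.numeric(ch1); y <- as.numeric(ch2)
  reg <- .orthogonal_regression(x, y)
  r2 <- suppressWarnings(stats::cor(x, y)^2)
  if (is.finite(r2) && r2 < 0.1)
    warning("channels are nearly uncorrelated (r^2 < 0.1); ",
            "the Costes regression is poorly determined")
  a <- reg["slope"]; b <- reg["intercept"]
  cand <- seq(max(x), min(x), length.out = n_levels)
  found <- NA_real_
  for (T in cand) {
    sel <- x < T & y < a * T + b
    if (sum(sel) < 2) next
    xs <- x[sel]; ys <- y[sel]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next
    if (stats::cor(xs, ys) <= 0) { found <- T; break }
  }
  fell <- is.na(found)
  if (fell) {
    warning("no threshold with non-positive below-threshold correlation; ",
            "thresholds set to the channel minima")
    out <- c(t1 = min(x), t2 = min(y))
  } else {
    out <- c(t1 = unname(found), t2 = unname(a * found + b))
  }
  attr(out, "slope") <- unname(a)
  attr(out, "intercept") <- unname(b)
  attr(out, "fell_to_minimum") <- fell
  out
}

#' Pearson colocalization with Costes automatic thresholding
#'
#' Computes the global PCC and the PCC restricted to pixels above the
#' Costes thresholds. The inclusion rule for the thresholded PCC is
#' `ch1 >= t1 | ch2 >= t2` (pixels above threshold in *either* channel, the
#' JACoP convention); an AND variant is available via `rule = "both"`.
#'
#' @param ch1,ch2 numeric matrices of identical shape.
#' @param rule `"either"` (default) or `"both"`.
#' @return object of class `glu_coloc`: list with `pcc_global`,
#'   `costes_thresholds` (`c(t1, t2)`), `pcc_above_threshold`,
#'   `n_pixels_used`, `unreliable` (fewer than 10 pixels above threshold).
#' @export
pcc_costes <- function(ch1, ch2, rule = c("either", "both")) {
  rule <- match.arg(rule)
  thr <- costes_threshold(ch1, ch2)
  sel <- if (rule == "either") ch1 >= thr[1] | ch2 >= thr[2] else
    ch1 >= thr[1] & ch2 >= thr[2]
  n <- sum(sel)
  pcc_above <- if (n >= 2) suppressWarnings(pearson(ch1, ch2, mask = sel)) else NA_real_
  unreliable <- n < 10
  if (unreliable)
    warning("fewer than 10 pixels above threshold; thresholded PCC unreliable")
  structure(list(pcc_global = pearson(ch1, ch2),
                 costes_thresholds = c(t1 = unname(thr[1]), t2 = unname(thr[2])),
                 pcc_above_threshold = pcc_above,
                 n_pixels_used = n,
                 unreliable = unreliable,
                 rule = rule),
            class = "glu_coloc")
}

#' @export
print.glu_coloc <- function(x, ...) {
  cat(sprintf("<glu_coloc> PCC global %.4f; Costes thresholds (%.4g, %.4g); ",
              x$pcc_global, x$costes_thresholds[1], x$costes_thresholds[2]))
  cat(sprintf("PCC above threshold %.4f over %d px%s\n",
              x$pcc_above_threshold, x$n_pixels_used,
              if (x$unreliable) " [unreliable]" else ""))
  invisible(x)
}

#' Colocalization over sampled rectangular regions
#'
#' Mirrors the practice of measuring PCC in a handful of randomly placed
#' rectangular regions of interest: `n_rect` axis-aligned rectangles of
#' size `rect_size` are sampled uniformly (seeded), [pcc_costes()] is
#' computed per rectangle, and a pooled result over the union of the
#' rectangles is reported. An explicit rectangle list (`data frame` with
#' columns `row0`, `col0`, `height`, `width`) may be given instead.
#'
#' @param ch1,ch2 numeric matrices of identical shape.
#' @param n_rect number of rectangles to sample (default 6).
#' @param rect_size height/width of sampled rectangles, px.
#' @param rectangles optional explicit rectangle table (overrides sampling).
#' @param seed RNG seed for the sampler.
#' @param rule see [pcc_costes()].
#' @return list with `per_rectangle` (data frame of rectangle coordinates
#'   and their PCC values) and `pooled` (a `glu_coloc` over the union).
#' @export
coloc_rectangles <- function(ch1, ch2, n_rect = 6L, rect_size = c(64L, 64L),
                             rectangles = NULL, seed = 1L,
                             rule = c("either", "both")) {
  rule <- match.arg(rule)
  d <- dim(ch1)
  if (is.null(rectangles)) {
    if (length(rect_size) == 1L) rect_size <- rep(rect_size, 2)
    rect_size <- pmin(rect_size, d)
    rectangles <- with_seed(seed, data.frame(
      row0 = floor(runif(n_rect, 1, d[1] - rect_size[1] + 2)),
      col0 = floor(runif(n_rect, 1, d[2] - rect_size[2] + 2)),
      height = rect_size[1], width = rect_size[2]))
  }
  res <- list(); mask <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(nrow(rectangles))) {
    r <- rectangles[i, ]
    rr <- r$row0:(r$row0 + r$height - 1); cc <- r$col0:(r$col0 + r$width - 1)
    rr <- rr[rr >= 1 & rr <= d[1]]; cc <- cc[cc >= 1 & cc <= d[2]]
    mask[rr, cc] <- TRUE
    cl <- tryCatch(pcc_costes(ch1[rr, cc], ch2[rr, cc], rule = rule),
                   warning = function(w) suppressWarnings(
                     pcc_costes(ch1[rr, cc], ch2[rr, cc], rule = rule)))
    res[[i]] <- data.frame(rect = i, row0 = r$row0, col0 = r$col0,
                           height = r$height, width = r$width,
                           pcc_global = cl$pcc_global,
                           pcc_above_threshold = cl$pcc_above_threshold)
  }
  sel1 <- matrix(ch1[mask], ncol = 1); sel2 <- matrix(ch2[mask], ncol = 1)
  pooled <- suppressWarnings(pcc_costes(sel1, sel2, rule = rule))
  list(per_rectangle = do.call(rbind, res), pooled = pooled,
       rectangles = rectangles)
}
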