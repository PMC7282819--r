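# Cleavage/turnover kinetics: single-exponential-with-plateau fits of
# normalized band-intensity time courses, half-life reporting, and the
# ordinary linear regression used to relate synchronous and spontaneous
# release.

#' Fit a single exponential decay with plateau
#'
#' Least-squares fit of `value(t) = C + (A - C) * exp(-t / tau)` where `A`
#' is the value at `t = 0`, `C` the plateau and `tau` the time constant (in
#' the units of `time`). Starting values: `A` = first value, `C` = minimum
#' value, `tau` from a log-linear regression of `value - C`; `tau` is
#' constrained positive and the optimizer (Levenberg-Marquardt,
#' [minpack.lm::nlsLM()]) runs to a 1e-8 parameter tolerance.
#'
#' @param curve data frame with columns `time` and `value` (a decay curve;
#'   times non-negative and increasing), or a numeric vector of times if
#'   `values` is given separately.
#' @param values numeric values when `curve` is a time vector.
#' @param fix_plateau_to_zero fit `C = 0` (2-parameter model); normalized
#'   cleavage curves that decay to completion may use this.
#' @param allow_increasing fit an increasing series without error (by
#'   default a series whose trend rises is refused with instructions, since
#'   a decay model is being requested).
#' @return object of class `exp_decay_fit` with elements `amplitude`,
#'   `plateau`, `tau`, `t_half` (`tau * ln 2`), `r_squared`, `sigma`,
#'   `std_errors`, `fitted`, `residuals`, `data`, `fixed_plateau`.
#' @seealso [half_life()], [simulate_decay_series()]
#' @export
fit_single_exponential <- function(curve, values = NULL,
                                   fix_plateau_to_zero = FALSE,
                                   allow_increasing = FALSE) {
  if (is.data.frame(curve)) {
    if (!all(c("time", "value") %in% names(curve)))
      stop("`curve` needs columns `time` and `value`")
    t <- curve$time; y <- curve$value
  } else {
    t <- curve; y <- values
    if (is.null(y)) stop("`values` required when `curve` is a time vector")
  }
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  n_par <- if (fix_plateau_to_zero) 2L else 3L
  if (length(t) < n_par + 1L)
    stop("need at least ", n_par + 1L, " points for a ", n_par, "-parameter fit")
  if (stats::sd(y) == 0)
    stop("flat series: exponential parameters are not identifiable")
  fit_lm <- stats::lm(y ~ t)
  if (stats::coef(fit_lm)[2] > 0 && !allow_increasing) {
    warning("series trends upward; a decay model was requested")
    stop("refusing to fit a decay to an increasing series ",
         "(set allow_increasing = TRUE to force)")
  }

  # start values: log-linear estimate of tau below a provisional plateau,
  # plus a coarse multi-start grid so single bad noise draws cannot strand
  # the optimizer on a singular gradient
  span <- diff(range(t))
  rngy <- diff(range(y))
  A0 <- y[which.min(t)]
  C_guess <- min(y) - 0.05 * rngy
  pos <- y - C_guess > .Machine$double.eps^0.5 * max(abs(y), 1)
  tau_ll <- if (sum(pos) >= 3) {
    sl <- stats::coef(stats::lm(log(y[pos] - C_guess) ~ t[pos]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else NA_real_
  } else NA_real_
  tau_starts <- unique(pmax(stats::na.omit(c(tau_ll, span / 5, span / 2, 2 * span)),
                            span * 1e-4))
  C_starts <- if (fix_plateau_to_zero) 0 else
    unique(c(C_guess, 0, mean(y[t >= stats::quantile(t, 0.7)])))
  if (max(t) < min(tau_starts))
    warning("sampled times span less than one nominal tau; ",
            "the fit may be unreliable")

  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-8, maxiter = 500)
  df <- data.frame(t = t, y = y)
  best <- NULL; best_sse <- Inf
  for (tau0 in tau_starts) for (C0 in C_starts) {
    cand <- tryCatch(suppressWarnings({
      if (fix_plateau_to_zero)
        minpack.lm::nlsLM(y ~ A * exp(-t / tau), data = df,
                          start = list(A = A0, tau = tau0),
                          lower = c(A = -Inf, tau = .Machine$double.eps),
                          control = ctrl)
      else
        minpack.lm::nlsLM(y ~ C + (A - C) * exp(-t / tau), data = df,
                          start = list(A = A0, C = C0, tau = tau0),
                          lower = c(A = -Inf, C = -Inf,
                                    tau = .Machine$double.eps),
                          control = ctrl)
    }), error = function(e) NULL)
    if (!is.null(cand)) {
      sse <- sum(stats::residuals(cand)^2)
      if (sse < best_sse) { best <- cand; best_sse <- sse }
    }
  }
  if (is.null(best)) {
    # last resort: direct SSE minimization in log-tau, then one polish
    obj <- function(par) {
      C <- if (fix_plateau_to_zero) 0 else par[2]
      sum((y - (C + (par[1] - C) * exp(-t / exp(par[length(par)]))))^2)
    }
    p0 <- if (fix_plateau_to_zero) c(A0, log(span / 3)) else
      c(A0, C_guess, log(span / 3))
    om <- stats::optim(p0, obj, control = list(maxit = 2000))
    st <- if (fix_plateau_to_zero)
      list(A = om$par[1], tau = exp(om$par[2])) else
      list(A = om$par[1], C = om$par[2], tau = exp(om$par[3]))
    best <- tryCatch(suppressWarnings(
      if (fix_plateau_to_zero)
        minpack.lm::nlsLM(y ~ A * exp(-t / tau), data = df, start = st,
                          lower = c(A = -Inf, tau = .Machine$double.eps),
                          control = ctrl)
      else
        minpack.lm::nlsLM(y ~ C + (A - C) * exp(-t / tau), data = df,
                          start = st,
                          lower = c(A = -Inf, C = -Inf,
                                    tau = .Machine$double.eps),
                          control = ctrl)), error = function(e) NULL)
  }
  if (is.null(best))
    stop("exponential fit did not converge from any starting point ",
         "(n = ", length(t), ", time span = ", signif(span, 4), ")")
  fit <- best
  cf <- stats::coef(fit)
  A <- unname(cf["A"])
  C <- if (fix_plateau_to_zero) 0 else unname(cf["C"])
  tau <- unname(cf["tau"])
  fitted_v <- C + (A - C) * exp(-t / tau)
  res <- y - fitted_v
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, n_par))
  structure(list(amplitude = A, plateau = C, tau = tau,
                 t_half = tau * log(2),
                 r_squared = 1 - ss_res / ss_tot,
                 sigma = sqrt(ss_res / max(length(t) - n_par, 1)),
                 std_errors = se,
                 fitted = fitted_v, residuals = res,
                 data = data.frame(time = t, value = y),
                 fixed_plateau = fix_plateau_to_zero,
                 nls = fit),
            class = "exp_decay_fit")
}

#' @export
print.exp_decay_fit <- function(x, digits = 4, ...) {
  cat("Single-exponential decay fit",
      if (x$fixed_plateau) " (plateau fixed at 0)", "\n", sep = "")
  cat(sprintf("  amplitude A = %.*g, plateau C = %.*g\n",
              digits, x$amplitude, digits, x$plateau))
  cat(sprintf("  tau = %.*g, t1/2 = %.*g (tau * ln 2)\n",
              digits, x$tau, digits, x$t_half))
  cat(sprintf("  R^2 = %.4f on %d points\n", x$r_squared, nrow(x$data)))
  invisible(x)
}

#' @export
coef.exp_decay_fit <- function(object, ...) {
  c(amplitude = object$amplitude, plateau = object$plateau, tau = object$tau)
}

#' @export
summary.exp_decay_fit <- function(object, ...) {
  cf <- coef(object)
  se <- object$std_errors
  if (object$fixed_plateau) se <- c(se[1], NA_real_, se[2])
  out <- data.frame(estimate = cf, std_error = unname(se))
  structure(list(coefficients = out, t_half = object$t_half,
                 r_squared = object$r_squared, sigma = object$sigma,
                 n = nrow(object$data)),
            class = "summary.exp_decay_fit")
}

#' @export
print.summary.exp_decay_fit <- function(x, ...) {
  print(x$coefficients)
  cat(sprintf("t1/2 = %.6g,  R^2 = %.4f,  residual sigma = %.4g,  n = %d\n",
              x$t_half, x$r_squared, x$sigma, x$n))
  invisible(x)
}

#' @export
predict.exp_decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time else
    if (is.data.frame(newdata)) newdata$time else newdata
  object$plateau + (object$amplitude - object$plateau) * exp(-t / object$tau)
}

#' @export
residuals.exp_decay_fit <- function(object, ...) object$residuals

#' @export
plot.exp_decay_fit <- function(x, ...) {
  plot(x$data$time, x$data$value, xlab = "time", ylab = "value",
       main = sprintf("exponential fit: tau = %.3g, R^2 = %.3f",
                      x$tau, x$r_squared), ...)
  tt <- seq(min(x$data$time), max(x$data$time), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Half-life of an exponential decay
#'
#' `t_half = tau * ln 2`, in the units of `tau`.
#'
#' @param tau positive time constant.
#' @return half-life, same units.
#' @export
half_life <- function(tau) {
  if (!is.numeric(tau) || any(tau <= 0)) stop("`tau` must be positive")
  tau * log(2)
}

#' Half-life rounded for reporting
#'
#' Convention used for printed half-lives in minutes: round to the integer
#' minute. The unrounded value is always available from [half_life()].
#'
#' @param tau positive time constant in minutes.
#' @return integer minutes.
#' @export
report_half_life_min <- function(tau) round(half_life(tau))

#' Ordinary least-squares line fit
#'
#' Simple linear regression `y = intercept + slope * x` with the two-sided
#' t-test of zero slope on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (>= 3 points; `x` must vary).
#' @return object of class `glu_linfit`: list with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, and the underlying `lm` fit.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("`x` is degenerate (all equal)")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) < 2) NA_real_ else sm$coefficients[2, 4]
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = p, n = length(x), lm = fit),
            class = "glu_linfit")
}

#' @export
print.glu_linfit <- function(x, ...) {
  cat(sprintf("Linear fit: y = %.4g + %.4g x  (r^2 = %.4f, p = %.4g, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}
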