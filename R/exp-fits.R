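## Exponential time-course fits shared by the SPR and fluorescence assays.

new_exp_fit <- function(s0, s1, k1, s2 = NA_real_, k2 = NA_real_,
                        t0, mode, n_components, reported_k, flags,
                        times, signals, fitted) {
  structure(list(s0 = s0, s1 = s1, s2 = s2, k1 = k1, k2 = k2, t0 = t0,
                 mode = mode, n_components = n_components,
                 reported_k = reported_k, flags = flags,
                 times = times, signals = signals, fitted = fitted),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("%s-exponential %s fit:\n",
              if (x$n_components == 2) "double" else "single", x$mode))
  cat(sprintf("  S0 = %.6g, S1 = %.6g, k1 = %.6g s^-1\n", x$s0, x$s1, x$k1))
  if (x$n_components == 2)
    cat(sprintf("  S2 = %.6g, k2 = %.6g s^-1\n", x$s2, x$k2))
  cat(sprintf("  reported k = %.6g s^-1\n", x$reported_k))
  for (fl in x$flags) cat("  flag:", fl, "\n")
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) {
  if (object$n_components == 2)
    c(s0 = object$s0, s1 = object$s1, k1 = object$k1,
      s2 = object$s2, k2 = object$k2)
  else c(s0 = object$s0, s1 = object$s1, k1 = object$k1)
}

#' @export
predict.exp_fit <- function(object, times = object$times, ...) {
  dt <- times - object$t0
  if (object$mode == "rise")
    return(object$s0 + object$s1 * (1 - exp(-object$k1 * dt)))
  out <- object$s0 + object$s1 * exp(-object$k1 * dt)
  if (object$n_components == 2) out <- out + object$s2 * exp(-object$k2 * dt)
  out
}

#' @export
residuals.exp_fit <- function(object, ...) object$signals - object$fitted

check_timecourse <- function(times, signals, min_points) {
  if (length(times) != length(signals))
    stop("times and signals must have equal length", call. = FALSE)
  if (length(times) < min_points)
    stop(sprintf("need at least %d points", min_points), call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(signals)))
    stop("times and signals must be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
}

## crude rate guess from the signal's approach to its terminal level
guess_rate <- function(times, signals, mode) {
  span <- diff(range(times))
  tail_level <- if (mode == "rise") signals[length(signals)] else
    signals[length(signals)]
  amp <- signals[1] - tail_level
  resid <- abs(signals - tail_level)
  usable <- resid > 0.05 * max(abs(amp), .Machine$double.eps)
  if (sum(usable) >= 3 && abs(amp) > 0) {
    sl <- stats::coef(stats::lsfit(times[usable],
                                   log(resid[usable])))[2]
    k <- -sl
    if (is.finite(k) && k > 0) return(unname(k))
  }
  2 / span
}

#' Fit a single exponential decay or rise
#'
#' Fits `S = S0 + S1 exp(-k (t - t0))` (decay) or
#' `S = S0 + S1 (1 - exp(-k (t - t0)))` (rise) by nonlinear least squares
#' with the rate optimised in log space.
#'
#' @param times strictly increasing times, seconds.
#' @param signals observed signal (RU, mP, fluorescence, ...).
#' @param mode `"decay"` or `"rise"`.
#' @param t0 phase start; defaults to the first time point.
#' @return An object of class `"exp_fit"`; `reported_k` is the fitted rate.
#'   A constant input yields amplitude 0 and an `"amplitude zero"` flag with
#'   `reported_k = NA` (the rate is unidentifiable).
#' @examples
#' t <- 0:100
#' fit_single_exponential(t, 2 + 3 * exp(-0.05 * t))
#' @export
fit_single_exponential <- function(times, signals,
                                   mode = c("decay", "rise"),
                                   t0 = times[1]) {
  mode <- match.arg(mode)
  check_timecourse(times, signals, 4L)
  dt <- times - t0
  flags <- character()
  if (stats::sd(signals) < 1e-12 * max(1, abs(mean(signals)))) {
    flags <- "amplitude zero: rate unidentifiable"
    return(new_exp_fit(s0 = mean(signals), s1 = 0, k1 = NA_real_, t0 = t0,
                       mode = mode, n_components = 1L,
                       reported_k = NA_real_, flags = flags,
                       times = times, signals = signals,
                       fitted = rep(mean(signals), length(signals))))
  }
  k0 <- guess_rate(times, signals, mode)
  s_last <- signals[length(signals)]
  if (mode == "decay") {
    p0 <- c(s0 = s_last, s1 = signals[1] - s_last, logk = log(k0))
    model <- function(p) p[1] + p[2] * exp(-exp(p[3]) * dt)
  } else {
    p0 <- c(s0 = signals[1], s1 = s_last - signals[1], logk = log(k0))
    model <- function(p) p[1] + p[2] * (1 - exp(-exp(p[3]) * dt))
  }
  fit <- minpack.lm::nls.lm(
    par = p0, fn = function(p) signals - model(p),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  p <- fit$par
  k <- exp(p[["logk"]])
  new_exp_fit(s0 = p[["s0"]], s1 = p[["s1"]], k1 = k, t0 = t0, mode = mode,
              n_components = 1L, reported_k = k, flags = flags,
              times = times, signals = signals, fitted = model(p))
}

#' Fit a double exponential decay with the population-reporting rule
#'
#' Fits `S = S0 + S1 exp(-k1 (t - t0)) + S2 exp(-k2 (t - t0))` to account
#' for host populations with different dissociation kinetics; components
#' are ordered so `k1 >= k2`.  The reported rate constant corresponds to
#' the faster and higher-amplitude exponential.  When the faster component
#' has the lower amplitude, the faster rate is still reported provided its
#' amplitude is at least 25% of the total, otherwise the higher-amplitude
#' rate is reported, and either way the conflict is flagged.  When only one
#' population is clearly present (near-equal rates or one vanishing
#' amplitude) the fit collapses to a single exponential.
#'
#' @inheritParams fit_single_exponential
#' @param collapse_ratio rate ratio `k1/k2` below which the two components
#'   are considered a single population.
#' @param min_amp_frac amplitude fraction below which a component is
#'   considered absent.
#' @return An object of class `"exp_fit"` with `n_components` 1 or 2.
#' @examples
#' t <- seq(0, 2000, by = 5)
#' s <- 1 + 0.7 * exp(-0.1 * t) + 0.3 * exp(-0.001 * t)
#' fit_double_exponential(t, s)
#' @export
fit_double_exponential <- function(times, signals, t0 = times[1],
                                   collapse_ratio = 1.5,
                                   min_amp_frac = 0.01) {
  check_timecourse(times, signals, 6L)
  single <- fit_single_exponential(times, signals, "decay", t0 = t0)
  if (length(single$flags)) return(single)
  dt <- times - t0
  model <- function(p) p[1] + p[2] * exp(-exp(p[3]) * dt) +
    p[4] * exp(-exp(p[5]) * dt)
  ## start from the single-exponential solution split into a faster and a
  ## slower component
  starts <- list(
    c(s0 = single$s0, s1 = single$s1 / 2, logk1 = log(single$k1 * 5),
      s2 = single$s1 / 2, logk2 = log(single$k1 / 5)),
    c(s0 = single$s0, s1 = single$s1 * 0.8, logk1 = log(single$k1 * 2),
      s2 = single$s1 * 0.2, logk2 = log(single$k1 / 20)),
    c(s0 = single$s0, s1 = single$s1 * 0.2, logk1 = log(single$k1 * 20),
      s2 = single$s1 * 0.8, logk2 = log(single$k1 / 2)))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(minpack.lm::nls.lm(
      par = p0, fn = function(p) signals - model(p),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || sum(fit$fvec^2) < best$sse))
      best <- list(par = fit$par, sse = sum(fit$fvec^2))
  }
  p <- best$par
  k <- exp(c(p[["logk1"]], p[["logk2"]]))
  s <- c(p[["s1"]], p[["s2"]])
  ord <- order(k, decreasing = TRUE)   # k1 is the faster component
  k <- k[ord]; s <- s[ord]
  amp_frac <- abs(s) / sum(abs(s))
  if (k[1] / k[2] < collapse_ratio || any(amp_frac < min_amp_frac)) {
    single$flags <- c(single$flags,
                      "collapsed to single exponential: one host population")
    return(single)
  }
  flags <- character()
  if (amp_frac[1] >= 0.25) {
    reported <- k[1]
    if (amp_frac[1] < amp_frac[2])
      flags <- paste("faster component has the lower amplitude",
                     sprintf("(%.0f%% of total); reporting the faster rate",
                             100 * amp_frac[1]))
  } else {
    reported <- k[2]
    flags <- paste("faster component amplitude below 25% of total;",
                   "reporting the higher-amplitude (slower) rate")
  }
  pp <- c(p[["s0"]], s[1], log(k[1]), s[2], log(k[2]))
  new_exp_fit(s0 = p[["s0"]], s1 = s[1], k1 = k[1], s2 = s[2], k2 = k[2],
              t0 = t0, mode = "decay", n_components = 2L,
              reported_k = reported, flags = flags,
              times = times, signals = signals, fitted = model(pp))
}

#' Fit a kinetic-competition polarization time course
#'
#' Single-exponential rise fit for fluorescence-polarization competition
#' measurements, `P = P0 + P1 (1 - exp(-k_app t))`.
#'
#' @param times seconds after the start of the measurement.
#' @param polarizations polarization values, mP.
#' @return An `"exp_fit"` object (rise mode, `t0 = 0` scale of the input).
#' @export
fit_competition_timecourse <- function(times, polarizations) {
  fit_single_exponential(times, polarizations, mode = "rise",
                         t0 = times[1])
}

#' Fit a sigmoid baseline drift
#'
#' Fits `S = S1 / (1 + exp(-k (t - t_half))) + S0`, the slow instrument
#' drift observed in long FRET time courses, so it can be subtracted from
#' measurement channels.
#'
#' @inheritParams fit_single_exponential
#' @return An object of class `"drift_fit"` with coefficients `s0`, `s1`,
#'   `k` (s^-1) and `t_half` (s).  A constant input is returned with
#'   amplitude pinned to 0 and flagged.
#' @seealso [subtract_drift]
#' @export
fit_baseline_drift <- function(times, signals) {
  check_timecourse(times, signals, 5L)
  if (stats::sd(signals) < 1e-12 * max(1, abs(mean(signals)))) {
    return(structure(list(s0 = mean(signals), s1 = 0, k = NA_real_,
                          t_half = NA_real_,
                          flags = "amplitude zero: no drift detected",
                          times = times, signals = signals,
                          fitted = rep(mean(signals), length(signals))),
                     class = "drift_fit"))
  }
  rising <- signals[length(signals)] >= signals[1]
  s0 <- if (rising) min(signals) else max(signals)
  s1 <- if (rising) diff(range(signals)) else -diff(range(signals))
  mid <- s0 + s1 / 2
  t_half0 <- times[which.min(abs(signals - mid))]
  span <- diff(range(times))
  model <- function(p)
    p[2] / (1 + exp(-exp(p[3]) * (times - p[4]))) + p[1]
  best <- NULL
  for (k0 in c(2 / span, 10 / span, 50 / span)) {
    p0 <- c(s0 = s0, s1 = s1, logk = log(k0), t_half = t_half0)
    fit <- tryCatch(minpack.lm::nls.lm(
      par = p0, fn = function(p) signals - model(p),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || sum(fit$fvec^2) < best$sse))
      best <- list(par = fit$par, sse = sum(fit$fvec^2))
  }
  p <- best$par
  structure(list(s0 = p[["s0"]], s1 = p[["s1"]], k = exp(p[["logk"]]),
                 t_half = p[["t_half"]], flags = character(),
                 times = times, signals = signals, fitted = model(p)),
            class = "drift_fit")
}

#' @export
print.drift_fit <- function(x, ...) {
  cat("sigmoid baseline-drift fit:\n")
  cat(sprintf("  S0 = %.6g, S1 = %.6g, k = %.6g s^-1, t_half = %.6g s\n",
              x$s0, x$s1, x$k, x$t_half))
  for (fl in x$flags) cat("  flag:", fl, "\n")
  invisible(x)
}

#' @export
coef.drift_fit <- function(object, ...) {
  c(s0 = object$s0, s1 = object$s1, k = object$k, t_half = object$t_half)
}

#' @export
predict.drift_fit <- function(object, times = object$times, ...) {
  if (object$s1 == 0) return(rep(object$s0, length(times)))
  object$s1 / (1 + exp(-object$k * (times - object$t_half))) + object$s0
}

#' Subtract a fitted baseline drift from a time course
#'
#' @param drift a [fit_baseline_drift] result.
#' @param times times of the signal to correct.
#' @param signals signal values to correct.
#' @return Drift-corrected signal vector.
#' @export
subtract_drift <- function(drift, times, signals) {
  stopifnot(inherits(drift, "drift_fit"))
  signals - predict(drift, times = times)
}
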