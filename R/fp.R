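## Fluorescence-polarization equilibrium binding analysis.

#' Fluorescence polarization from channel intensities
#'
#' `P = (I_parallel - I_perpendicular) / (I_parallel + I_perpendicular)
#' x 1000`, in millipolarization units.
#'
#' @param parallel parallel-channel fluorescence intensity.
#' @param perpendicular perpendicular-channel fluorescence intensity.
#' @return Polarization in mP.  Vectorised.
#' @examples
#' polarization(2, 1)   # 1000/3 mP
#' @export
polarization <- function(parallel, perpendicular) {
  tot <- parallel + perpendicular
  if (any(!is.finite(tot)) || any(tot <= 0))
    stop("total intensity must be positive", call. = FALSE)
  (parallel - perpendicular) / tot * 1000
}

#' Exact bound fraction from the quadratic binding isotherm
#'
#' Fraction of labelled effector bound to the host at total concentrations
#' `[A]` (host) and `[C]` (effector), from the exact solution of the
#' equilibrium mass balance:
#' `f = ( [A] + [C] + K_D - sqrt(([A]+[C]+K_D)^2 - 4 [A][C]) ) / (2 [C])`.
#' Evaluated in the algebraically equivalent product form
#' `f = 2 [A] / (s + sqrt(s^2 - 4 [A][C]))`, `s = [A]+[C]+K_D`, which does
#' not suffer catastrophic cancellation when `[A][C] << s^2`.
#'
#' @param host_conc total host concentration `[A]`, molar.
#' @param effector_conc total labelled-effector concentration `[C]`, molar
#'   (> 0).
#' @param kd dissociation constant, molar.
#' @return Bound fraction in [0, 1].  Vectorised over `host_conc`.
#' @examples
#' bound_fraction(1e-8, 1e-10, 1e-8)
#' @export
bound_fraction <- function(host_conc, effector_conc, kd) {
  if (any(!is.finite(host_conc)) || any(host_conc < 0) ||
      !is.finite(effector_conc) || effector_conc <= 0 ||
      !is.finite(kd) || kd < 0)
    stop("need host >= 0, effector > 0, kd >= 0", call. = FALSE)
  s <- host_conc + effector_conc + kd
  disc <- pmax(s^2 - 4 * host_conc * effector_conc, 0)
  f <- 2 * host_conc / (s + sqrt(disc))
  pmin(pmax(f, 0), 1)
}

#' Fit the exact binding isotherm to a polarization titration
#'
#' Fits `P = P0 + P1 f_bound([A]; [C], K_D)` by nonlinear least squares
#' with `K_D` optimised in log space.  When the fitted `K_D` falls below
#' the labelled-effector concentration the affinity is too strong to be
#' measured by this titration and the result is censored: `kd` is reported
#' as the upper bound `[C]`.
#'
#' @param host_concs host concentrations per well, molar (the titration
#'   series).
#' @param polarizations measured polarization, mP.
#' @param effector_conc constant labelled-effector concentration, molar.
#' @return An object of class `"isotherm_fit"` with elements `p0`, `p1`
#'   (mP), `kd` (molar), `kd_fit` (the uncensored estimate) and `censored`.
#' @examples
#' a <- 1e-6 / 2^(0:23)
#' p <- 50 + 150 * bound_fraction(a, 1e-10, 1e-8)
#' fit_isotherm(a, p, 1e-10)
#' @export
fit_isotherm <- function(host_concs, polarizations, effector_conc) {
  if (length(host_concs) != length(polarizations))
    stop("host_concs and polarizations must have equal length",
         call. = FALSE)
  if (length(host_concs) < 6L)
    stop("need at least 6 titration points", call. = FALSE)
  if (any(!is.finite(polarizations)))
    stop("polarizations must be finite", call. = FALSE)
  flags <- character()
  if (stats::sd(polarizations) <
      1e-10 * max(1, abs(mean(polarizations)))) {
    return(structure(list(p0 = mean(polarizations), p1 = 0, kd = NA_real_,
                          kd_fit = NA_real_, censored = FALSE,
                          effector_conc = effector_conc,
                          flags = "flat titration: K_D unidentifiable",
                          fitted = rep(mean(polarizations),
                                       length(polarizations))),
                     class = "isotherm_fit"))
  }
  model <- function(p)
    p[1] + p[2] * bound_fraction(host_concs, effector_conc, exp(p[3]))
  pos <- host_concs[host_concs > 0]
  best <- NULL
  for (kd0 in stats::quantile(pos, c(0.1, 0.5, 0.9), names = FALSE)) {
    p0 <- c(p0 = min(polarizations),
            p1 = max(polarizations) - min(polarizations),
            logkd = log(kd0))
    fit <- tryCatch(minpack.lm::nls.lm(
      par = p0, fn = function(p) polarizations - model(p),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || sum(fit$fvec^2) < best$sse))
      best <- list(par = fit$par, sse = sum(fit$fvec^2))
  }
  p <- best$par
  kd_fit <- exp(p[["logkd"]])
  censored <- kd_fit < effector_conc
  structure(list(p0 = p[["p0"]], p1 = p[["p1"]],
                 kd = if (censored) effector_conc else kd_fit,
                 kd_fit = kd_fit, censored = censored,
                 effector_conc = effector_conc, flags = flags,
                 fitted = model(p)),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat("FP binding isotherm fit:\n")
  cat(sprintf("  P0 = %.6g mP, P1 = %.6g mP\n", x$p0, x$p1))
  if (isTRUE(x$censored))
    cat(sprintf("  K_D < %.3g M (censored: tighter than measurable at this [C])\n",
                x$effector_conc))
  else cat(sprintf("  K_D = %.6g M\n", x$kd))
  for (fl in x$flags) cat("  flag:", fl, "\n")
  invisible(x)
}

#' @export
coef.isotherm_fit <- function(object, ...) {
  c(p0 = object$p0, p1 = object$p1, kd = object$kd)
}
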