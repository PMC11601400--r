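## Global fit of all dissociation cycles.
##
## Free parameters: the five network rates (optimised in log space), the
## three response amplitudes (log space), the responsive fraction (logit
## space, bounded to [0,1]), and per-cycle scale factors for cycles >= 2
## (log space; f_1 = 1 is the gauge).  The objective is the unweighted sum
## of squared residuals over every point of every cycle, minimised by
## Levenberg-Marquardt with multi-start jittered initialisation because the
## effector on/off pair (k_on,BA:C, k_off,BA:C) tends to covary tightly and
## creates flat valleys.

fd_param_names <- function(n_cycles, fixed) {
  nm <- c("k_off_B_A", "k_on_BA_C", "k_off_BA_C", "k_off_B_AC", "k_off_B_An",
          "a_BA", "a_BAC", "a_BAn", "f_responsive",
          if (n_cycles >= 2) paste0("f_cycle_", 2:n_cycles))
  setdiff(nm, names(fixed))
}

## Box bounds in optimiser space keep rates physical and stop runaway along
## the flat plateau where every complex decays within one sample interval.
fd_opt_bounds <- function(free_names, max_resp) {
  lower <- numeric(length(free_names)); upper <- numeric(length(free_names))
  for (i in seq_along(free_names)) {
    nm <- free_names[i]
    if (nm == "f_responsive") { lower[i] <- -20; upper[i] <- 20 }
    else if (nm == "k_on_BA_C") { lower[i] <- log(1e-2); upper[i] <- log(1e12) }
    else if (startsWith(nm, "k_")) { lower[i] <- log(1e-10); upper[i] <- log(1e3) }
    else if (startsWith(nm, "a_")) {
      lower[i] <- log(1e-6 * max(max_resp, 1))
      upper[i] <- log(1e3 * max(max_resp, 1))
    } else { lower[i] <- log(1e-3); upper[i] <- log(1e3) }  # f_cycle_n
  }
  list(lower = lower, upper = upper)
}

## Data-driven starting values: each cycle's dissociation curve is fitted
## with a (double falling back to single) exponential, giving an empirical
## effective-rate profile across effector concentrations.  Its fast end
## approximates k_off,B:AC, its slow end k_off,B:A, and the concentration
## of half-maximal rate sets the k_on scale.
fd_default_init <- function(dataset) {
  schedule <- dataset$schedule
  ks <- vapply(dataset$cycles, function(cy) {
    fit <- tryCatch(fit_double_exponential(cy$time_s, cy$response_RU),
                    error = function(e) tryCatch(
                      fit_single_exponential(cy$time_s, cy$response_RU),
                      error = function(e2) NULL))
    if (is.null(fit) || !is.finite(fit$reported_k)) NA_real_
    else fit$reported_k
  }, numeric(1))
  concs <- schedule$effector_concs
  ok <- is.finite(ks) & ks > 0
  if (sum(ok) >= 2) {
    k_fast <- max(ks[ok]); k_slow <- min(ks[ok])
    mid <- sqrt(k_fast * k_slow)
    c_half <- concs[ok][which.min(abs(ks[ok] - mid))]
    if (c_half <= 0) c_half <- max(concs) / 10
    k_on0 <- max(k_fast / c_half, 1)
  } else {
    k_fast <- 0.05; k_slow <- 1e-4; k_on0 <- 1e5
  }
  a0 <- dataset$cycles[[1]]$response_RU[1]
  if (!is.finite(a0) || a0 <= 0)
    a0 <- max(vapply(dataset$cycles, function(cy) max(cy$response_RU),
                     numeric(1)))
  out <- list(k_off_B_A = max(k_slow / 2, 1e-8), k_on_BA_C = k_on0,
              k_off_BA_C = k_fast / 10, k_off_B_AC = k_fast,
              k_off_B_An = max(k_slow / 10, 1e-8),
              a_BA = a0, a_BAC = a0, a_BAn = a0, f_responsive = 0.9)
  if (schedule$n_cycles >= 2)
    for (n in 2:schedule$n_cycles) out[[paste0("f_cycle_", n)]] <- 1
  out
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

## transform a named natural-scale parameter list to the optimiser scale
fd_to_opt <- function(par) {
  out <- par
  for (nm in names(out)) {
    out[[nm]] <- if (nm == "f_responsive") {
      logit(min(max(par[[nm]], 1e-8), 1 - 1e-8))
    } else {
      log(max(par[[nm]], 1e-300))
    }
  }
  unlist(out)
}

fd_from_opt <- function(opt) {
  out <- as.list(opt)
  for (nm in names(out)) {
    out[[nm]] <- if (nm == "f_responsive") inv_logit(opt[[nm]])
                 else exp(opt[[nm]])
  }
  out
}

## assemble full natural-scale parameter list from free + fixed parts
fd_full_par <- function(free, fixed, n_cycles) {
  par <- c(free, fixed)
  f_cycle <- rep(1, n_cycles)
  if (n_cycles >= 2)
    for (n in 2:n_cycles) f_cycle[n] <- par[[paste0("f_cycle_", n)]]
  list(rates = rate_constants(par$k_off_B_A, par$k_on_BA_C, par$k_off_BA_C,
                              par$k_off_B_AC, par$k_off_B_An),
       response = response_model(par$a_BA, par$a_BAC, par$a_BAn,
                                 f_cycle, par$f_responsive))
}

## Lean numeric model evaluation for the optimisation loop: identical
## mathematics to simulate_cycles (cycle recursion + closed-form
## propagation + response map) without container validation overhead.
## Evaluated directly on each cycle's observed time grid.
fd_model_responses <- function(par_full, schedule, cycles) {
  r <- unclass(par_full$rates)
  resp <- par_full$response
  f_cycle <- rep_len(c(resp$f_cycle,
                       rep(1, max(0, schedule$n_cycles -
                                       length(resp$f_cycle)))),
                     schedule$n_cycles)
  fr <- resp$f_responsive
  kban <- r[["k_off_B_An"]]
  out <- vector("list", schedule$n_cycles)
  ba_f <- 0; ban_f <- 0
  for (n in seq_len(schedule$n_cycles)) {
    b_f <- 1 - ba_f - ban_f
    ba0 <- ba_f + fr * b_f
    ban0 <- ban_f + (1 - fr) * b_f
    m <- dissociation_matrix(r, schedule$effector_concs[n])
    tt <- cycles[[n]]$time_s
    w <- schedule$dissociation_window[n]
    y <- expm2_action(m$a, m$b, m$cc, m$d, c(0, ba0), c(tt, w))
    np <- length(tt)
    ban_t <- ban0 * exp(-kban * c(tt, w))
    out[[n]] <- f_cycle[n] *
      (resp$a_BA * y[seq_len(np), "ba"] +
       resp$a_BAC * y[seq_len(np), "bac"] +
       resp$a_BAn * ban_t[seq_len(np)])
    ba_f <- y[np + 1L, "ba"] + y[np + 1L, "bac"]  # terminal BAC folds in
    ban_f <- ban_t[np + 1L]
  }
  out
}

#' Globally fit the cycle model to all SPR dissociation cycles
#'
#' Fits the chip-occupancy ODE model, the initial-value recursion with an
#' accumulating effector-unresponsive host population, and the response map
#' jointly to the dissociation curves of every cycle by nonlinear
#' least-squares (Levenberg-Marquardt, rates in log space, responsive
#' fraction bounded to [0,1] via a logit transform, first per-cycle scale
#' factor pinned to 1).  The effector binding parameters `k_on,BA:C` and
#' `k_off,BA:C` tend to covary tightly and cannot usually be determined
#' individually from these fits; the result carries a covariance flag
#' rather than failing.
#'
#' @param dataset an [spr_dataset] with at least two cycles at distinct
#'   effector concentrations.
#' @param init optional named list of natural-scale starting values for any
#'   of `k_off_B_A`, `k_on_BA_C`, `k_off_BA_C`, `k_off_B_AC`, `k_off_B_An`,
#'   `a_BA`, `a_BAC`, `a_BAn`, `f_responsive`, `f_cycle_2`, ...
#' @param fixed optional named list pinning parameters at fixed values.
#' @param n_starts number of jittered multi-start initialisations.
#' @param jitter multiplicative jitter factor applied to rate/amplitude
#'   starts (each start multiplies by `jitter^u`, `u ~ U(-1, 1)`).
#' @param maxiter maximum Levenberg-Marquardt iterations per start.
#' @return An object of class `"spr_global_fit"` with elements `rates`
#'   (a [rate_constants]), `response` (a [response_model]), `residual_sse`,
#'   `per_cycle_residuals`, `covariance_flags`, `converged`, and `fitted`
#'   (list of fitted response vectors).
#' @seealso [simulate_cycles], [fold_change], [effective_rate]
#' @export
fit_global <- function(dataset, init = NULL, fixed = NULL,
                       n_starts = 5, jitter = 3, maxiter = 400) {
  stopifnot(inherits(dataset, "spr_dataset"))
  schedule <- dataset$schedule
  if (schedule$n_cycles < 2L)
    stop("global fit needs >= 2 cycles for identifiability", call. = FALSE)
  if (all(schedule$effector_concs == 0))
    stop(paste("all cycles have zero effector: k_off,B:AC is not",
               "identifiable"), call. = FALSE)
  fixed <- as.list(fixed)
  free_names <- fd_param_names(schedule$n_cycles, fixed)

  max_resp <- max(vapply(dataset$cycles, function(cy)
    max(cy$response_RU), numeric(1)))
  start <- utils::modifyList(fd_default_init(dataset), as.list(init))
  start <- start[fd_param_names(schedule$n_cycles, list())]

  resid_for <- function(free_nm, fix) {
    n_out <- sum(vapply(dataset$cycles, nrow, integer(1)))
    function(opt_par) {
      free <- fd_from_opt(stats::setNames(opt_par, free_nm))
      full <- tryCatch(fd_full_par(free, fix, schedule$n_cycles),
                       error = function(e) NULL)
      if (is.null(full)) return(rep(1e6, n_out))
      model <- fd_model_responses(full, schedule, dataset$cycles)
      unlist(lapply(seq_along(model), function(n)
        dataset$cycles[[n]]$response_RU - model[[n]]))
    }
  }

  run_lm <- function(st, free_nm, fix) {
    bounds <- fd_opt_bounds(free_nm, max_resp)
    p0 <- pmin(pmax(fd_to_opt(st[free_nm]), bounds$lower), bounds$upper)
    tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_for(free_nm, fix),
                         lower = bounds$lower, upper = bounds$upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-15, ptol = 1e-12)),
      error = function(e) NULL)
  }

  ## parameters held at their starting values during the first stage:
  ## amplitudes and per-cycle factors, so the rate parameters settle into
  ## the right basin before the response map is released
  stage1_held <- intersect(free_names,
                           c("a_BA", "a_BAC", "a_BAn",
                             grep("^f_cycle_", free_names, value = TRUE)))

  ## starts: the supplied init, the data-driven init, then jittered copies
  data_init <- utils::modifyList(fd_default_init(dataset),
                                 list())[names(start)]
  best <- NULL
  for (s in seq_len(n_starts)) {
    st <- if (s == 1) start else if (s == 2) data_init
          else if (s %% 2 == 1) start else data_init
    if (s > 2) {             # jitter subsequent starts multiplicatively
      for (nm in free_names) {
        if (nm == "f_responsive") {
          st[[nm]] <- min(max(st[[nm]] + stats::runif(1, -0.2, 0.2), 0.01),
                          0.99)
        } else {
          st[[nm]] <- st[[nm]] * jitter^stats::runif(1, -1, 1)
        }
      }
    }
    ## route A: all parameters free from the start
    fit_a <- run_lm(st, free_names, fixed)
    ## route B: staged — rates + responsive fraction first with the
    ## response map pinned, then everything free
    fn1 <- setdiff(free_names, stage1_held)
    f1 <- run_lm(st, fn1, c(fixed, st[stage1_held]))
    st_b <- if (is.null(f1)) st else
      utils::modifyList(st, fd_from_opt(stats::setNames(f1$par, fn1)))
    fit_b <- run_lm(st_b, free_names, fixed)
    for (fit in Filter(Negate(is.null), list(fit_a, fit_b))) {
      sse <- sum(fit$fvec^2)
      ok <- fit$info %in% 1:4
      if (is.null(best) || sse < best$sse)
        best <- list(fit = fit, sse = sse, converged = ok)
    }
    if (is.null(best)) next
    if (ok && sse < (1e-8 * max_resp)^2 *
          sum(vapply(dataset$cycles, nrow, integer(1)))) break
  }
  if (is.null(best))
    stop("global fit failed in every start", call. = FALSE)

  ## polish: restarting Levenberg-Marquardt resets its trust region, which
  ## often drains the last of the residual in flat valleys
  repeat {
    st_p <- fd_from_opt(stats::setNames(best$fit$par, free_names))
    fit_p <- run_lm(st_p, free_names, fixed)
    if (is.null(fit_p)) break
    sse_p <- sum(fit_p$fvec^2)
    if (sse_p < best$sse * (1 - 1e-8)) {
      best <- list(fit = fit_p, sse = sse_p,
                   converged = fit_p$info %in% 1:4)
    } else break
  }

  free <- fd_from_opt(stats::setNames(best$fit$par, free_names))
  full <- fd_full_par(free, fixed, schedule$n_cycles)
  model <- fd_model_responses(full, schedule, dataset$cycles)
  per_cycle <- vapply(seq_along(model), function(n)
    sum((dataset$cycles[[n]]$response_RU - model[[n]])^2), numeric(1))

  flags <- character()
  konC <- full$rates[["k_on_BA_C"]] * max(schedule$effector_concs)
  if (konC > 20 * max(full$rates[["k_off_B_A"]], full$rates[["k_off_B_AC"]]))
    flags <- c(flags, paste(
      "k_on,BA:C and k_off,BA:C tightly covary at these concentrations;",
      "only partner off-rates are well determined"))
  if (!best$converged)
    flags <- c(flags, "optimizer did not report convergence in any start")

  structure(list(rates = full$rates, response = full$response,
                 residual_sse = sum(per_cycle),
                 per_cycle_residuals = per_cycle,
                 covariance_flags = flags,
                 converged = best$converged,
                 n_starts_used = n_starts,
                 fitted = model,
                 dataset = dataset,
                 weighting = "unweighted SSE across all cycles"),
            class = "spr_global_fit")
}

#' @export
print.spr_global_fit <- function(x, ...) {
  cat("Global fit of multi-cycle SPR dissociation data\n")
  print(x$rates)
  cat(sprintf("  f_responsive = %.4f\n", x$response$f_responsive))
  cat(sprintf("  residual SSE = %.6g RU^2 over %d cycles%s\n",
              x$residual_sse, length(x$per_cycle_residuals),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  for (fl in x$covariance_flags) cat("  note:", fl, "\n")
  invisible(x)
}

#' @export
coef.spr_global_fit <- function(object, ...) {
  c(unclass(object$rates),
    a_BA = object$response$a_BA, a_BAC = object$response$a_BAC,
    a_BAn = object$response$a_BAn,
    f_responsive = object$response$f_responsive,
    stats::setNames(object$response$f_cycle[-1],
                    paste0("f_cycle_",
                           seq_along(object$response$f_cycle)[-1])))
}

#' @export
summary.spr_global_fit <- function(object, ...) {
  print(object)
  cat("\nPer-cycle residual SSE (RU^2):\n")
  print(stats::setNames(object$per_cycle_residuals,
                        paste0("cycle_",
                               seq_along(object$per_cycle_residuals))))
  cat(sprintf("\nEffector-induced off-rate fold change: %.4g\n",
              fold_change(object)))
  invisible(object)
}

#' @export
fitted.spr_global_fit <- function(object, ...) object$fitted

#' @export
residuals.spr_global_fit <- function(object, ...) {
  lapply(seq_along(object$fitted), function(n)
    object$dataset$cycles[[n]]$response_RU - object$fitted[[n]])
}

#' Effector-induced off-rate fold change
#'
#' The headline metric of a facilitated-dissociation design: the ratio of
#' the partner off-rate from the strained ternary complex to the base
#' off-rate from the binary complex, `k_off,B:AC / k_off,B:A`.
#'
#' @param result an [spr_global_fit] or a [rate_constants] object.
#' @return Dimensionless ratio (> 0).
#' @export
fold_change <- function(result) {
  rates <- if (inherits(result, "spr_global_fit")) result$rates
           else as_rate_constants(result)
  if (rates[["k_off_B_A"]] <= 0)
    stop("fold change undefined: k_off,B:A is zero", call. = FALSE)
  rates[["k_off_B_AC"]] / rates[["k_off_B_A"]]
}
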