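#' Multi-cycle SPR experiment schedule
#'
#' Describes the repeated cycles of host association and induced
#' dissociation: one dissociation window per cycle, each under flow of a
#' fixed effector concentration, typically a two-fold serial dilution.
#'
#' @param effector_concs effector concentration per cycle, molar.
#' @param dissociation_window length of each dissociation phase, seconds.
#'   Recycled to the number of cycles.
#' @param sample_interval sampling interval, seconds.
#' @return An object of class `"cycle_schedule"`.
#' @examples
#' cycle_schedule(5e-6 / 2^(0:5))         # 6 cycles, 2-fold dilution
#' @export
cycle_schedule <- function(effector_concs, dissociation_window = 600,
                           sample_interval = 1) {
  n <- length(effector_concs)
  if (n < 1L || any(!is.finite(effector_concs)) || any(effector_concs < 0))
    stop("effector_concs must be non-negative and non-empty", call. = FALSE)
  w <- rep_len(dissociation_window, n)
  if (any(w <= 0) || sample_interval <= 0)
    stop("windows and sample interval must be positive", call. = FALSE)
  structure(list(n_cycles = n, effector_concs = as.numeric(effector_concs),
                 dissociation_window = w,
                 sample_interval = sample_interval),
            class = "cycle_schedule")
}

#' @export
print.cycle_schedule <- function(x, ...) {
  cat(sprintf("SPR schedule: %d cycles, windows %s s, sampling %.3g s\n",
              x$n_cycles, paste(unique(x$dissociation_window), collapse = "/"),
              x$sample_interval))
  cat("  effector (M):", format(x$effector_concs, digits = 3), "\n")
  invisible(x)
}

#' SPR response model
#'
#' Maps modelled chip occupancies to instrument response:
#' `S = f_n (a_BA [BA] + a_BAC [BAC] + a_BAn [BAn])` for cycle `n`.
#' The first per-cycle scale factor is fixed to 1 as the gauge, making the
#' amplitudes identifiable.
#'
#' @param a_BA,a_BAC,a_BAn response amplitudes, RU per unit occupancy.
#' @param f_cycle per-cycle scale factors; the first must be 1.
#' @param f_responsive fraction of freshly loaded host responsive to the
#'   effector, in [0, 1].
#' @return An object of class `"response_model"`.
#' @export
response_model <- function(a_BA = 100, a_BAC = a_BA, a_BAn = a_BA,
                           f_cycle = 1, f_responsive = 1) {
  amps <- c(a_BA = a_BA, a_BAC = a_BAC, a_BAn = a_BAn)
  if (any(!is.finite(amps)) || any(amps < 0))
    stop("amplitudes must be finite and non-negative", call. = FALSE)
  if (length(f_cycle) < 1L || abs(f_cycle[1] - 1) > 1e-12)
    stop("the first per-cycle scale factor is the gauge and must equal 1",
         call. = FALSE)
  if (!is.finite(f_responsive) || f_responsive < 0 || f_responsive > 1)
    stop("f_responsive must lie in [0, 1]", call. = FALSE)
  structure(list(a_BA = a_BA, a_BAC = a_BAC, a_BAn = a_BAn,
                 f_cycle = as.numeric(f_cycle),
                 f_responsive = f_responsive),
            class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf(
    "response model: a_BA=%.4g a_BAC=%.4g a_BAn=%.4g RU, f_responsive=%.3f\n",
    x$a_BA, x$a_BAC, x$a_BAn, x$f_responsive))
  cat("  cycle scale factors:", format(x$f_cycle, digits = 4), "\n")
  invisible(x)
}

#' Initial chip states for each dissociation cycle
#'
#' Implements the initial-value recursion of the multi-cycle experiment.
#' Between cycles the chip is re-loaded with host: free capture sites left
#' at the end of cycle `n-1` refill, a fraction `f_responsive` into the
#' effector-responsive BA pool and the remainder into the unresponsive BAn
#' pool, which therefore accumulates across cycles.  Each cycle starts with
#' `[BAC] = 0` (the effector washes out between cycles; any terminal ternary
#' complex is folded into the BA pool).
#'
#' @param rates a [rate_constants] object.
#' @param schedule a [cycle_schedule].
#' @param f_responsive responsive fraction in [0, 1].
#' @return List of [chip_state] objects, one per cycle.
#' @export
cycle_initial_states <- function(rates, schedule, f_responsive = 1) {
  rates <- as_rate_constants(rates)
  stopifnot(inherits(schedule, "cycle_schedule"))
  if (!is.finite(f_responsive) || f_responsive < 0 || f_responsive > 1)
    stop("f_responsive must lie in [0, 1]", call. = FALSE)
  ba_final <- 0
  ban_final <- 0
  out <- vector("list", schedule$n_cycles)
  for (n in seq_len(schedule$n_cycles)) {
    b_final <- 1 - ba_final - ban_final
    ba0 <- ba_final + f_responsive * b_final
    ban0 <- ban_final + (1 - f_responsive) * b_final
    out[[n]] <- chip_state(ba = ba0, bac = 0, ban = ban0,
                           b = max(1 - ba0 - ban0, 0))
    ## propagate this cycle's window to obtain the next cycle's finals;
    ## terminal BAC is folded back into BA (effector washout)
    tr <- propagate_dissociation(
      rates, schedule$effector_concs[n], out[[n]],
      times = c(0, schedule$dissociation_window[n]))
    last <- tr$states[nrow(tr$states), ]
    ba_final <- last[["ba"]] + last[["bac"]]
    ban_final <- last[["ban"]]
  }
  out
}

cycle_time_grid <- function(schedule, n) {
  seq(0, schedule$dissociation_window[n], by = schedule$sample_interval)
}

#' Simulate a noise-free multi-cycle SPR dataset
#'
#' Forward-simulates the dissociation phase of every cycle from the cycle
#' recursion and maps occupancies to response units through the response
#' model.
#'
#' @inheritParams cycle_initial_states
#' @param response a [response_model]; its `f_responsive` drives the cycle
#'   recursion and its amplitudes and per-cycle factors the response map.
#' @return An [spr_dataset] with one `(time_s, response_RU)` series per
#'   cycle.
#' @examples
#' r <- rate_constants(1e-4, 1e5, 1e-3, 0.1, 1e-5)
#' sch <- cycle_schedule(5e-6 / 2^(0:5))
#' ds <- simulate_cycles(r, sch, response_model(a_BA = 100, f_responsive = 0.9))
#' ds
#' @export
simulate_cycles <- function(rates, schedule, response = response_model()) {
  rates <- as_rate_constants(rates)
  stopifnot(inherits(schedule, "cycle_schedule"),
            inherits(response, "response_model"))
  f_cycle <- rep_len(c(response$f_cycle,
                       rep(1, max(0, schedule$n_cycles -
                                       length(response$f_cycle)))),
                     schedule$n_cycles)
  inits <- cycle_initial_states(rates, schedule, response$f_responsive)
  cycles <- vector("list", schedule$n_cycles)
  for (n in seq_len(schedule$n_cycles)) {
    times <- cycle_time_grid(schedule, n)
    tr <- propagate_dissociation(rates, schedule$effector_concs[n],
                                 inits[[n]], times)
    s <- f_cycle[n] * (response$a_BA * tr$states[, "ba"] +
                       response$a_BAC * tr$states[, "bac"] +
                       response$a_BAn * tr$states[, "ban"])
    cycles[[n]] <- data.frame(time_s = times, response_RU = s)
  }
  spr_dataset(cycles, schedule, meta = list(source = "simulate_cycles"))
}

#' Multi-cycle SPR dataset container
#'
#' @param cycles list of data frames with columns `time_s`, `response_RU`,
#'   one per cycle, times strictly increasing from 0.
#' @param schedule the [cycle_schedule] the data were collected under.
#' @param meta free-form provenance list.
#' @return An object of class `"spr_dataset"`.
#' @export
spr_dataset <- function(cycles, schedule, meta = list()) {
  stopifnot(inherits(schedule, "cycle_schedule"))
  if (length(cycles) != schedule$n_cycles)
    stop("number of cycle series must match the schedule", call. = FALSE)
  for (cy in cycles) {
    if (!all(c("time_s", "response_RU") %in% names(cy)))
      stop("each cycle needs columns time_s and response_RU", call. = FALSE)
    if (nrow(cy) < 2L || any(diff(cy$time_s) <= 0) || cy$time_s[1] != 0)
      stop("cycle times must strictly increase from 0", call. = FALSE)
    if (anyNA(cy$response_RU))
      stop("cycle responses must not contain NA", call. = FALSE)
  }
  structure(list(cycles = cycles, schedule = schedule, meta = meta),
            class = "spr_dataset")
}

#' @export
print.spr_dataset <- function(x, ...) {
  np <- vapply(x$cycles, nrow, integer(1))
  cat(sprintf("SPR dataset: %d cycles, %d points total\n",
              length(x$cycles), sum(np)))
  print(x$schedule)
  invisible(x)
}
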