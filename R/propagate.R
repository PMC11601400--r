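## Closed-form propagation of the dissociation-phase chip kinetics.
##
## During a dissociation window the effector concentration [C] is constant
## (continuous flow), so the coupled BA/BAC pair obeys a 2x2 linear
## constant-coefficient ODE system and BAn decays as an independent single
## exponential.  In (bac, ba) order the coefficient matrix is
##
##   A = | -(k_off,B:AC + k_off,BA:C)        k_on,BA:C [C]      |
##       |        k_off,BA:C          -(k_off,B:A + k_on,BA:C [C]) |
##
## whose discriminant (a-d)^2 + 4bc is non-negative for non-negative rates,
## so both eigenvalues are real and the system can be solved exactly.

## 2x2 matrix exponential action: exp(A t) %*% y0 for a vector of times.
## Returns a matrix with columns (bac, ba).  Falls back to the limit-correct
## repeated-eigenvalue branch when the eigenvalues are near-degenerate.
expm2_action <- function(a, b, cc, d, y0, times) {
  tr <- -(a + d)
  disc <- (a - d)^2 + 4 * b * cc
  disc <- max(disc, 0)
  sq <- sqrt(disc)
  l1 <- (tr + sq) / 2
  l2 <- (tr - sq) / 2
  if (abs(l1 - l2) < 1e-12 * max(abs(l1), abs(l2), 1e-300)) {
    ## exp(At) = e^{lt} (I + (A - lI) t) for a repeated eigenvalue l
    l <- (l1 + l2) / 2
    e <- exp(l * times)
    n11 <- -a - l; n12 <- b; n21 <- cc; n22 <- -d - l
    bac <- e * (y0[1] + times * (n11 * y0[1] + n12 * y0[2]))
    ba  <- e * (y0[2] + times * (n21 * y0[1] + n22 * y0[2]))
    return(cbind(bac = bac, ba = ba))
  }
  ## spectral projectors: exp(At) = e^{l1 t} P1 + e^{l2 t} P2,
  ## P1 = (A - l2 I)/(l1 - l2), P2 = (A - l1 I)/(l2 - l1)
  dl <- l1 - l2
  p1_11 <- (-a - l2) / dl; p1_12 <- b / dl
  p1_21 <- cc / dl;        p1_22 <- (-d - l2) / dl
  p2_11 <- (-a - l1) / -dl; p2_12 <- b / -dl
  p2_21 <- cc / -dl;        p2_22 <- (-d - l1) / -dl
  e1 <- exp(l1 * times)
  e2 <- exp(l2 * times)
  bac <- e1 * (p1_11 * y0[1] + p1_12 * y0[2]) +
         e2 * (p2_11 * y0[1] + p2_12 * y0[2])
  ba  <- e1 * (p1_21 * y0[1] + p1_22 * y0[2]) +
         e2 * (p2_21 * y0[1] + p2_22 * y0[2])
  cbind(bac = bac, ba = ba)
}

## Coefficient-matrix entries for given rates and effector concentration.
dissociation_matrix <- function(rates, effector_conc) {
  konC <- rates[["k_on_BA_C"]] * effector_conc
  list(a = rates[["k_off_B_AC"]] + rates[["k_off_BA_C"]],
       b = konC,
       cc = rates[["k_off_BA_C"]],
       d = rates[["k_off_B_A"]] + konC)
}

#' Propagate chip occupancies through a dissociation window
#'
#' Solves the dissociation-phase kinetics exactly: the coupled BA/BAC pair
#' via eigendecomposition of its 2x2 constant-coefficient system, and the
#' unresponsive BAn population as an independent single exponential.  Free
#' capture sites are reported as the capacity not held by any complex.
#'
#' @param rates a [rate_constants] object.
#' @param effector_conc effector concentration during the window, molar;
#'   constant over the window (flow conditions).
#' @param state0 initial [chip_state]; defaults to all host partner-bound
#'   and responsive.
#' @param times strictly increasing time grid in seconds starting at 0.
#' @return An object of class `"occupancy_trajectory"`: list with `times`
#'   and an occupancy matrix `states` (columns `ba`, `bac`, `ban`, `b`).
#' @examples
#' r <- rate_constants(1e-4, 1e5, 1e-3, 0.1, 1e-5)
#' tr <- propagate_dissociation(r, 1e-6, times = 0:600)
#' head(tr$states)
#' @export
propagate_dissociation <- function(rates, effector_conc,
                                   state0 = chip_state(), times) {
  rates <- as_rate_constants(rates)
  if (!is.numeric(effector_conc) || length(effector_conc) != 1L ||
      !is.finite(effector_conc) || effector_conc < 0)
    stop("effector_conc must be a single non-negative number (molar)",
         call. = FALSE)
  if (!inherits(state0, "chip_state")) state0 <- do.call(chip_state, as.list(state0))
  if (length(times) < 1L || times[1] != 0 ||
      (length(times) > 1L && any(diff(times) <= 0)))
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  m <- dissociation_matrix(rates, effector_conc)
  y <- expm2_action(m$a, m$b, m$cc, m$d,
                    c(state0[["bac"]], state0[["ba"]]), times)
  ban <- state0[["ban"]] * exp(-rates[["k_off_B_An"]] * times)
  states <- cbind(ba = pmax(y[, "ba"], 0), bac = pmax(y[, "bac"], 0),
                  ban = pmax(ban, 0))
  states <- cbind(states, b = pmax(1 - rowSums(states), 0))
  structure(list(times = times, states = states,
                 effector_conc = effector_conc, rates = rates),
            class = "occupancy_trajectory")
}

#' @export
print.occupancy_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf(
    "occupancy trajectory: %d points over %.4g s at [C] = %.3g M\n",
    n, x$times[n], x$effector_conc))
  cat(sprintf("  bound fraction (ba+bac): %.4g -> %.4g\n",
              sum(x$states[1, c("ba", "bac")]),
              sum(x$states[n, c("ba", "bac")])))
  invisible(x)
}

## total partner-bound fraction ba(t)+bac(t) from (bac0, ba0), closed form
bound_fraction_at <- function(rates, effector_conc, t, bac0 = 0, ba0 = 1) {
  m <- dissociation_matrix(rates, effector_conc)
  y <- expm2_action(m$a, m$b, m$cc, m$d, c(bac0, ba0), t)
  y[, "bac"] + y[, "ba"]
}

#' Half-time of the partner-host interaction
#'
#' Solves the simplified dissociation system (no unresponsive population,
#' initial state `[BAC] = 0`, `[BA] = 1`) for the time at which the total
#' partner-bound fraction `[BA](t) + [BAC](t)` falls to one half.  Because
#' total bound occupancy is strictly decreasing whenever either partner
#' off-rate is positive, the root is unique and bracketed root-finding on
#' the closed-form solution is safe.
#'
#' @inheritParams propagate_dissociation
#' @param rel_tol relative tolerance on the located half-time.
#' @return Half-time in seconds.
#' @examples
#' r <- rate_constants(1e-4, 1e5, 1e-3, 0.1)
#' half_time(r, 0)            # ln(2) / k_off,B:A
#' half_time(r, 1e-6)         # accelerated by the effector
#' @export
half_time <- function(rates, effector_conc, rel_tol = 1e-10) {
  rates <- as_rate_constants(rates)
  if (rates[["k_off_B_A"]] <= 0 && rates[["k_off_B_AC"]] <= 0)
    stop("system does not dissociate: both partner off-rates are zero",
         call. = FALSE)
  f <- function(t) bound_fraction_at(rates, effector_conc, t) - 0.5
  koff <- c(rates[["k_off_B_A"]], rates[["k_off_B_AC"]])
  hi <- 10 * log(2) / min(koff[koff > 0])
  while (f(hi) > 0) hi <- hi * 4
  stats::uniroot(f, c(0, hi), tol = hi * rel_tol)$root
}

#' Effective rate of the full facilitated-dissociation process
#'
#' For each effector concentration, computes the half-time of total
#' partner-bound occupancy and converts it to an effective first-order rate
#' `k_eff = ln(2) / t_half`.  As `[C] -> 0`, `k_eff` approaches the base
#' off-rate `k_off,B:A`; as `[C] -> Inf` it approaches the partner off-rate
#' from the ternary complex, `k_off,B:AC`.
#'
#' @inheritParams half_time
#' @param effector_concs vector of effector concentrations, molar.
#' @return Numeric vector of effective rates, s^-1, ordered as the input.
#' @examples
#' r <- rate_constants(1e-4, 1e5, 1e-3, 0.1)
#' effective_rate(r, c(0, 1e-8, 1e-7, 1e-6))
#' @export
effective_rate <- function(rates, effector_concs, rel_tol = 1e-10) {
  vapply(effector_concs,
         function(cc) log(2) / half_time(rates, cc, rel_tol = rel_tol),
         numeric(1))
}
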