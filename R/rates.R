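#' Rate constants of the facilitated-dissociation network
#'
#' Bundles the four first-order and one second-order rate constants that
#' govern dissociation of a partner (B) from a chip-immobilised host (A) in
#' the presence of an effector (C).  The network comprises the binary
#' partner-host complex (BA), the strained ternary complex (BAC) formed when
#' the effector binds, and an effector-unresponsive host population (BAn)
#' that accumulates across SPR cycles.
#'
#' @param k_off_B_A partner off-rate from the binary complex, s^-1.
#' @param k_on_BA_C effector on-rate to the partner-host complex, M^-1 s^-1.
#' @param k_off_BA_C effector off-rate from the ternary complex, s^-1.
#' @param k_off_B_AC partner off-rate from the ternary complex, s^-1.
#' @param k_off_B_An partner off-rate from the unresponsive host, s^-1.
#'
#' @return An object of class `"rate_constants"`: a named numeric vector of
#'   the five rates.
#' @examples
#' rate_constants(k_off_B_A = 1e-4, k_on_BA_C = 1e5, k_off_BA_C = 1e-3,
#'                k_off_B_AC = 0.1, k_off_B_An = 1e-5)
#' @export
rate_constants <- function(k_off_B_A, k_on_BA_C, k_off_BA_C,
                           k_off_B_AC, k_off_B_An = 0) {
  r <- c(k_off_B_A = k_off_B_A, k_on_BA_C = k_on_BA_C,
         k_off_BA_C = k_off_BA_C, k_off_B_AC = k_off_B_AC,
         k_off_B_An = k_off_B_An)
  if (!is.numeric(r) || length(r) != 5L || any(!is.finite(r)))
    stop("all five rate constants must be finite numbers", call. = FALSE)
  if (any(r < 0))
    stop("rate constants must be non-negative", call. = FALSE)
  structure(r, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Facilitated-dissociation rate constants:\n")
  cat(sprintf("  k_off,B:A   %-12.4g s^-1      (partner off binary)\n",
              x[["k_off_B_A"]]))
  cat(sprintf("  k_on,BA:C   %-12.4g M^-1 s^-1 (effector on)\n",
              x[["k_on_BA_C"]]))
  cat(sprintf("  k_off,BA:C  %-12.4g s^-1      (effector off ternary)\n",
              x[["k_off_BA_C"]]))
  cat(sprintf("  k_off,B:AC  %-12.4g s^-1      (partner off ternary)\n",
              x[["k_off_B_AC"]]))
  cat(sprintf("  k_off,B:An  %-12.4g s^-1      (partner off unresponsive)\n",
              x[["k_off_B_An"]]))
  invisible(x)
}

as_rate_constants <- function(x) {
  if (inherits(x, "rate_constants")) return(x)
  x <- unlist(x)
  rate_constants(x[["k_off_B_A"]], x[["k_on_BA_C"]], x[["k_off_BA_C"]],
                 x[["k_off_B_AC"]],
                 if ("k_off_B_An" %in% names(x)) x[["k_off_B_An"]] else 0)
}

#' Chip occupancy state
#'
#' Occupancies are dimensionless fractions of total chip capture capacity,
#' normalised so that `ba + bac + ban + b = 1` at the start of an experiment.
#'
#' @param ba occupancy of the binary partner-host complex.
#' @param bac occupancy of the ternary complex.
#' @param ban occupancy of unresponsive-host complex.
#' @param b free capture-site fraction.
#' @param tol slack permitted on the capacity bound.
#' @return An object of class `"chip_state"`.
#' @export
chip_state <- function(ba = 1, bac = 0, ban = 0, b = 0, tol = 1e-8) {
  s <- c(ba = ba, bac = bac, ban = ban, b = b)
  if (any(!is.finite(s)) || any(s < -tol))
    stop("chip occupancies must be finite and non-negative", call. = FALSE)
  if (sum(s) > 1 + 1e-6)
    stop("total chip occupancy exceeds capacity", call. = FALSE)
  structure(pmax(s, 0), class = "chip_state")
}

#' @export
print.chip_state <- function(x, ...) {
  cat(sprintf("chip state: [BA]=%.4g [BAC]=%.4g [BAn]=%.4g [B]=%.4g\n",
              x[["ba"]], x[["bac"]], x[["ban"]], x[["b"]]))
  invisible(x)
}
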