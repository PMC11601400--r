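## Hooke's-law strain-energy model linking deformation geometry to the
## off-rate enhancement observed in facilitated dissociation experiments.

GAS_CONSTANT_KCAL <- 1.9872e-3   # kcal mol^-1 K^-1

#' Experimental strain energy from off-rate enhancement
#'
#' The strain stored in the ternary complex destabilises the partner
#' interface; approximating the partner on-rate as unchanged, the strain
#' energy follows from the off-rate ratio:
#' `ddG = R T ln( k_off,B:AC / k_off,B:A,unstrained )`.
#' Because switch fusions can form extra stabilising contacts with the
#' partner that persist in the ternary complex, the unstrained off-rate is
#' floored: the smaller of `k_base_offrate` and the measured `k_off_B_A` is
#' used.  The default floor of 2e-4 s^-1 is close to the partner off-rate
#' from an unhindered binder fusion (9e-5 s^-1).
#'
#' @param k_off_B_AC accelerated partner off-rate from the ternary complex,
#'   s^-1 (> 0).
#' @param k_off_B_A measured base partner off-rate, s^-1 (> 0).
#' @param k_base_offrate floor for the unstrained off-rate, s^-1.
#' @param temperature Kelvin; experiments at 25 C by default.
#' @return Strain energy in kcal/mol.
#' @examples
#' experimental_strain_energy(0.4, 2e-4)    # ~ R T ln(2000)
#' @export
experimental_strain_energy <- function(k_off_B_AC, k_off_B_A,
                                       k_base_offrate = 2e-4,
                                       temperature = 298.15) {
  if (any(!is.finite(c(k_off_B_AC, k_off_B_A))) ||
      any(c(k_off_B_AC, k_off_B_A) <= 0))
    stop("off-rates must be positive and finite", call. = FALSE)
  unstrained <- pmin(k_base_offrate, k_off_B_A)
  GAS_CONSTANT_KCAL * temperature * log(k_off_B_AC / unstrained)
}

#' Spring constant from strain energy and pivot angle
#'
#' Hooke's law for the ternary-complex spring:
#' `k = ddG / (theta - theta0)^2`.
#'
#' @param ddg strain energy, kcal/mol.
#' @param theta deformation (pivot) angle `theta - theta0`, radians (> 0).
#' @return Spring constant in kcal/mol/rad^2.
#' @export
spring_constant <- function(ddg, theta) {
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("spring constant undefined for theta <= 0", call. = FALSE)
  ddg / theta^2
}

#' One design's strain record
#'
#' @param design_id label.
#' @param k_off_B_AC,k_off_B_A partner off-rates, s^-1.
#' @param theta pivot angle, radians.
#' @param sin_phi perpendicularity of the deformation, in [0, 1].
#' @param k_base_offrate,temperature passed to
#'   [experimental_strain_energy].
#' @return A one-row data frame with the derived `ddg_exp` (kcal/mol) and
#'   `spring_k` (kcal/mol/rad^2).
#' @export
strain_record <- function(design_id, k_off_B_AC, k_off_B_A, theta, sin_phi,
                          k_base_offrate = 2e-4, temperature = 298.15) {
  ddg <- experimental_strain_energy(k_off_B_AC, k_off_B_A, k_base_offrate,
                                    temperature)
  data.frame(design_id = design_id, k_off_B_AC = k_off_B_AC,
             k_off_B_A = k_off_B_A, theta = theta, sin_phi = sin_phi,
             ddg_exp = ddg,
             spring_k = if (theta > 0) ddg / theta^2 else NA_real_)
}

#' Fit the perpendicularity-linear spring model over a design cohort
#'
#' The spring constant is assumed linear in the perpendicularity of the
#' deformation to the secondary structure elements, so the predicted strain
#' energy is `ddG_pred = (m sin(phi) + b) (theta - theta0)^2`.  The
#' parameters `m` and `b` are fitted by least squares of predicted against
#' experimental strain energy across the cohort (the strain-energy
#' expression itself is fitted, not the spring-constant-vs-sin(phi) line,
#' which remains available as a diagnostic).  Linear in `m` and `b`, the
#' fit reduces to ordinary least squares on the regressors
#' `sin(phi) theta^2` and `theta^2`.
#'
#' @param records data frame with columns `theta`, `sin_phi` and `ddg_exp`
#'   (e.g. rows from [strain_record]); at least 3 records with
#'   `theta > 0`.
#' @param temperature Kelvin, recorded in the model.
#' @param k_base_offrate the unstrained off-rate floor used to build the
#'   records, s^-1, recorded in the model.
#' @return An object of class `"spring_model"` with coefficients `m`, `b`
#'   (kcal/mol/rad^2), the cohort `r_squared` of predicted vs experimental
#'   strain energy, and fitted values.
#' @seealso [predicted_strain_energy]
#' @export
fit_spring_model <- function(records, temperature = 298.15,
                             k_base_offrate = 2e-4) {
  req <- c("theta", "sin_phi", "ddg_exp")
  if (!all(req %in% names(records)))
    stop("records need columns theta, sin_phi, ddg_exp", call. = FALSE)
  records <- records[records$theta > 0, , drop = FALSE]
  if (nrow(records) < 3L)
    stop("need >= 3 records with theta > 0 to fit the spring model",
         call. = FALSE)
  x1 <- records$sin_phi * records$theta^2
  x2 <- records$theta^2
  if (stats::sd(records$sin_phi) < 1e-12)
    stop("all sin_phi identical: slope m is unidentifiable", call. = FALSE)
  fit <- stats::lm.fit(cbind(m = x1, b = x2), records$ddg_exp)
  m <- fit$coefficients[["m"]]
  b <- fit$coefficients[["b"]]
  pred <- m * x1 + b * x2
  ss_res <- sum((records$ddg_exp - pred)^2)
  ss_tot <- sum((records$ddg_exp - mean(records$ddg_exp))^2)
  structure(list(m = m, b = b, k_base_offrate = k_base_offrate,
                 temperature = temperature,
                 r_squared = 1 - ss_res / ss_tot,
                 n = nrow(records), records = records, fitted = pred),
            class = "spring_model")
}

#' @export
print.spring_model <- function(x, ...) {
  cat("perpendicularity-linear spring model:\n")
  cat(sprintf("  k(phi) = m sin(phi) + b,  m = %.6g, b = %.6g kcal/mol/rad^2\n",
              x$m, x$b))
  cat(sprintf("  R^2 (predicted vs experimental ddG) = %.4f over %d designs\n",
              x$r_squared, x$n))
  cat(sprintf("  unstrained off-rate floor %.3g s^-1, T = %.2f K\n",
              x$k_base_offrate, x$temperature))
  invisible(x)
}

#' @export
coef.spring_model <- function(object, ...) c(m = object$m, b = object$b)

#' Predicted strain energy from deformation geometry
#'
#' `ddG_pred = (m sin(phi) + b) (theta - theta0)^2` for a fitted spring
#' model.  Also available as the `predict` method of `"spring_model"`.
#'
#' @param model a [fit_spring_model] result (or any list with `m`, `b`).
#' @param geometry a [pivot_decomposition] result, or a list/data frame
#'   with `theta` and `sin_phi`.
#' @return Predicted strain energy, kcal/mol.
#' @export
predicted_strain_energy <- function(model, geometry) {
  theta <- geometry$theta
  sin_phi <- geometry$sin_phi
  (model$m * sin_phi + model$b) * theta^2
}

#' @export
predict.spring_model <- function(object, geometry = object$records, ...) {
  predicted_strain_energy(object, geometry)
}
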