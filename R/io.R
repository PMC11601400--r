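## Plain-text serialisation: long-format CSV for cycle data with a JSON
## schedule sidecar, and JSON (explicit units) for fit results.

#' Write / read a multi-cycle SPR dataset
#'
#' The cycle series are stored as long-format CSV with columns `cycle`,
#' `time_s`, `response_RU`; the schedule (effector concentrations in molar,
#' windows and sampling in seconds) travels in a JSON sidecar.
#'
#' @param dataset an [spr_dataset].
#' @param path CSV path.
#' @param sidecar schedule JSON path; defaults to `<path>.schedule.json`.
#' @return `write_spr_dataset` invisibly returns the paths;
#'   `read_spr_dataset` returns the [spr_dataset].
#' @export
write_spr_dataset <- function(dataset, path,
                              sidecar = paste0(path, ".schedule.json")) {
  stopifnot(inherits(dataset, "spr_dataset"))
  long <- do.call(rbind, lapply(seq_along(dataset$cycles), function(n)
    cbind(cycle = n, dataset$cycles[[n]])))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  sch <- dataset$schedule
  jsonlite::write_json(
    list(n_cycles = sch$n_cycles,
         effector_concs_M = sch$effector_concs,
         dissociation_window_s = sch$dissociation_window,
         sample_interval_s = sch$sample_interval,
         meta = dataset$meta),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = path, sidecar = sidecar))
}

#' @rdname write_spr_dataset
#' @export
read_spr_dataset <- function(path, sidecar = paste0(path, ".schedule.json")) {
  long <- utils::read.csv(path)
  sch_js <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  schedule <- cycle_schedule(sch_js$effector_concs_M,
                             sch_js$dissociation_window_s,
                             sch_js$sample_interval_s)
  cycles <- lapply(seq_len(schedule$n_cycles), function(n)
    long[long$cycle == n, c("time_s", "response_RU")])
  cycles <- lapply(cycles, function(cy) { rownames(cy) <- NULL; cy })
  spr_dataset(cycles, schedule,
              meta = if (is.null(sch_js$meta)) list() else sch_js$meta)
}

#' Serialise a global fit result to JSON
#'
#' Writes the fitted rates, response model, responsive fraction and
#' residual diagnostics with explicit unit fields.
#'
#' @param fit an [spr_global_fit].
#' @param path output JSON path.
#' @export
write_global_fit <- function(fit, path) {
  stopifnot(inherits(fit, "spr_global_fit"))
  jsonlite::write_json(global_fit_as_list(fit), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

global_fit_as_list <- function(fit) {
  list(
    rates = list(
      k_off_B_A = list(value = fit$rates[["k_off_B_A"]], unit = "s^-1"),
      k_on_BA_C = list(value = fit$rates[["k_on_BA_C"]],
                       unit = "M^-1 s^-1"),
      k_off_BA_C = list(value = fit$rates[["k_off_BA_C"]], unit = "s^-1"),
      k_off_B_AC = list(value = fit$rates[["k_off_B_AC"]], unit = "s^-1"),
      k_off_B_An = list(value = fit$rates[["k_off_B_An"]], unit = "s^-1")),
    response = list(
      a_BA = list(value = fit$response$a_BA, unit = "RU"),
      a_BAC = list(value = fit$response$a_BAC, unit = "RU"),
      a_BAn = list(value = fit$response$a_BAn, unit = "RU"),
      f_cycle = list(value = fit$response$f_cycle, unit = "dimensionless"),
      f_responsive = list(value = fit$response$f_responsive,
                          unit = "dimensionless")),
    fold_change = list(value = fold_change(fit), unit = "dimensionless"),
    residual_sse = list(value = fit$residual_sse, unit = "RU^2"),
    per_cycle_residual_sse = list(value = fit$per_cycle_residuals,
                                  unit = "RU^2"),
    covariance_flags = as.list(fit$covariance_flags),
    converged = fit$converged,
    weighting = fit$weighting)
}
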