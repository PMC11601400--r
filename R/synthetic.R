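## Seeded synthetic-data generators emulating each experiment the analysis
## consumes.  Every generator is deterministic under a fixed seed and
## attaches the generating ground truth as the "truth" attribute so
## downstream recovery tests never peek at the generator internals.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit(if (is.null(old))
      rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv()))
  }
  force(expr)
}

#' Noise specification for synthetic data
#'
#' @param kind `"gaussian-absolute"` (sd in signal units) or
#'   `"gaussian-relative-to-max"` (sd as a fraction of the maximum
#'   noise-free signal).
#' @param sd standard deviation (units per `kind`); >= 0.
#' @param seed integer seed; identical seeds give bit-identical data.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(kind = c("gaussian-relative-to-max",
                                "gaussian-absolute"),
                       sd = 0.01, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.finite(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
  structure(list(kind = kind, sd = sd, seed = as.integer(seed)),
            class = "noise_spec")
}

noise_sd_abs <- function(noise, reference_max) {
  if (noise$kind == "gaussian-absolute") noise$sd
  else noise$sd * reference_max
}

#' Generate a noisy multi-cycle SPR dataset with known ground truth
#'
#' Simulates the dissociation phases of a multi-cycle induced-dissociation
#' experiment (two-fold effector dilution by default) from the cycle model
#' and adds Gaussian noise.  Defaults mirror the experimental design the
#' model was built for: 6 cycles two-fold diluted from 5 uM effector,
#' 600 s dissociation windows sampled at 1 s, noise at 1% of the maximum
#' response.
#'
#' The default rates describe a moderate design (25-fold effector-induced
#' off-rate acceleration) whose effective-rate transition lies inside the
#' 32-fold dilution window, so that both partner off-rates are identifiable
#' from the simulated cycles — the situation the serial dilution is designed
#' to create.
#'
#' @param rates generating [rate_constants].
#' @param schedule a [cycle_schedule].
#' @param response a [response_model].
#' @param noise a [noise_spec]; sd 0 returns the noise-free simulation.
#' @return An [spr_dataset]; the generating parameters are attached as
#'   `attr(, "truth")` (list with `rates`, `response`, `schedule`).
#' @examples
#' ds <- generate_spr_dataset()
#' attr(ds, "truth")$rates
#' @export
generate_spr_dataset <- function(rates = rate_constants(2e-3, 3e4, 1e-3,
                                                        0.05, 1e-5),
                                 schedule = cycle_schedule(5e-6 / 2^(0:5)),
                                 response = response_model(
                                   a_BA = 100, f_responsive = 0.9),
                                 noise = noise_spec(sd = 0.01, seed = 1L)) {
  ds <- simulate_cycles(rates, schedule, response)
  max_resp <- max(vapply(ds$cycles, function(cy) max(cy$response_RU),
                         numeric(1)))
  sd_abs <- noise_sd_abs(noise, max_resp)
  if (sd_abs > 0) {
    ds$cycles <- with_seed(noise$seed, lapply(ds$cycles, function(cy) {
      cy$response_RU <- cy$response_RU +
        stats::rnorm(nrow(cy), sd = sd_abs)
      cy
    }))
  }
  ds$meta <- list(source = "generate_spr_dataset", noise = unclass(noise))
  attr(ds, "truth") <- list(rates = as_rate_constants(rates),
                            response = response, schedule = schedule)
  ds
}

#' Generate an apparent-rate concentration profile
#'
#' Draws a noisy `k_app` vs `[C]` profile from either the induced-fit
#' (linear) or conformational-selection (hyperbolic) law.
#'
#' @param mechanism `"induced_fit"` (linear) or
#'   `"conformational_selection"` (hyperbolic).
#' @param params named list: `k_on`, `k_off` for the linear law;
#'   `k_switch`, `k_base`, `K_half` for the hyperbolic law.
#' @param concs effector concentrations, molar.
#' @param noise a [noise_spec]; relative noise scales with the maximum
#'   noise-free `k_app`.
#' @return A [kapp_profile] with the truth attached as `attr(, "truth")`.
#' @export
generate_kapp_profile <- function(mechanism = c("induced_fit",
                                                "conformational_selection"),
                                  params, concs,
                                  noise = noise_spec(sd = 0.05, seed = 1L)) {
  mechanism <- match.arg(mechanism)
  kapps <- if (mechanism == "induced_fit") {
    params$k_on * concs + params$k_off
  } else {
    (params$k_switch - params$k_base) * concs / (params$K_half + concs) +
      params$k_base
  }
  sd_abs <- noise_sd_abs(noise, max(kapps))
  if (sd_abs > 0)
    kapps <- with_seed(noise$seed,
                       kapps + stats::rnorm(length(kapps), sd = sd_abs))
  pr <- kapp_profile(concs, kapps, source = mechanism)
  attr(pr, "truth") <- list(mechanism = mechanism, params = params)
  pr
}

#' Generate a fluorescence-polarization titration
#'
#' Noise-free values follow the exact quadratic isotherm
#' `P = P0 + P1 f_bound`; by default the host is titrated by two-fold
#' serial dilution through 24 wells, mirroring the standard plate design.
#'
#' @param p0 free-effector polarization, mP.
#' @param p1 bound-state polarization change, mP.
#' @param kd host-effector dissociation constant, molar.
#' @param effector_conc labelled-effector concentration, molar.
#' @param host_concs host concentrations; default 24-well two-fold series
#'   from 1 uM.
#' @param noise a [noise_spec]; relative noise scales with the full
#'   polarization range.
#' @return Data frame with columns `host_conc_M`, `polarization_mP`; truth
#'   attached as `attr(, "truth")`.
#' @export
generate_fp_titration <- function(p0 = 50, p1 = 150, kd, effector_conc,
                                  host_concs = 1e-6 / 2^(0:23),
                                  noise = noise_spec(sd = 0.02, seed = 1L)) {
  p <- p0 + p1 * bound_fraction(host_concs, effector_conc, kd)
  sd_abs <- noise_sd_abs(noise, max(abs(p - p0)))
  if (sd_abs > 0)
    p <- with_seed(noise$seed, p + stats::rnorm(length(p), sd = sd_abs))
  out <- data.frame(host_conc_M = host_concs, polarization_mP = p)
  attr(out, "truth") <- list(p0 = p0, p1 = p1, kd = kd,
                             effector_conc = effector_conc)
  out
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` radians about the unit vector `axis`.
#'
#' @param axis length-3 direction (normalised internally).
#' @param angle radians.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + sin(angle) * kx + (1 - cos(angle)) * (kx %*% kx)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

ideal_helix <- function(n, rise = 1.5, radius = 2.3,
                        twist = 100 * pi / 180) {
  i <- seq_len(n) - 1
  cbind(radius * cos(i * twist), radius * sin(i * twist), rise * i)
}

#' Generate a structure pair with known deformation geometry
#'
#' Builds a synthetic host (a random globular Calpha cloud carrying an
#' ideal alpha-helix over the declared helix range) and partner, then
#' creates the strained partner by rotating the clashing partner by a known
#' angle about a known located axis.  The whole strained complex is
#' additionally placed in a random rigid frame so the switch-alignment
#' step of [pivot_decomposition] is exercised, and optional isotropic
#' coordinate noise is added to the strained structure.
#'
#' @param n_residues partner size (Calpha count).
#' @param axis pivot axis direction (normalised internally).
#' @param point a point on the pivot axis, Angstrom.
#' @param angle deformation angle, radians.
#' @param helix_range residue indices of the binder helix within the host;
#'   >= 7 residues.
#' @param noise_sd isotropic Gaussian coordinate noise on the strained
#'   structure, Angstrom.
#' @param n_switch host size; must cover `helix_range`.
#' @param seed integer seed.
#' @return A [structure_pair]; `attr(, "truth")` holds the generating
#'   `angle`, unit `axis`, `point`, and the `sin_phi` implied by the
#'   constructed helix.
#' @export
generate_structure_pair <- function(n_residues = 50,
                                    axis = c(0, 0, 1),
                                    point = c(0, 0, 0),
                                    angle = 20 * pi / 180,
                                    helix_range = 11:24,
                                    noise_sd = 0,
                                    n_switch = 60,
                                    seed = 1L) {
  stopifnot(max(helix_range) <= n_switch)
  with_seed(seed, {
    u <- axis / sqrt(sum(axis^2))
    switch_ref <- matrix(stats::rnorm(n_switch * 3, sd = 8), n_switch, 3)
    ## embed an ideal helix in a random orientation over the helix range
    helix <- ideal_helix(length(helix_range))
    hr <- superpose(matrix(stats::rnorm(nrow(helix) * 3), ncol = 3),
                    matrix(stats::rnorm(nrow(helix) * 3), ncol = 3))
    helix_dir_frame <- hr$rotation      # random proper rotation
    switch_ref[helix_range, ] <- helix %*% t(helix_dir_frame) +
      matrix(stats::rnorm(3, sd = 5), length(helix_range), 3, byrow = TRUE)
    partner_clash <- matrix(stats::rnorm(n_residues * 3, sd = 6),
                            n_residues, 3) +
      matrix(c(25, 0, 0), n_residues, 3, byrow = TRUE)
    ## strained partner: rotate about the located pivot axis
    r <- rotation_about_axis(u, angle)
    partner_strained <- sweep(sweep(partner_clash, 2, point) %*% t(r),
                              2, point, `+`)
    ## place the strained complex in a random rigid frame
    frame_r <- rotation_about_axis(random_unit_vector(),
                                   stats::runif(1, 0, pi))
    frame_t <- stats::rnorm(3, sd = 30)
    switch_strained <- apply_rigid(switch_ref, frame_r, frame_t)
    partner_strained <- apply_rigid(partner_strained, frame_r, frame_t)
    if (noise_sd > 0) {
      switch_strained <- switch_strained +
        matrix(stats::rnorm(length(switch_strained), sd = noise_sd),
               nrow(switch_strained), 3)
      partner_strained <- partner_strained +
        matrix(stats::rnorm(length(partner_strained), sd = noise_sd),
               nrow(partner_strained), 3)
    }
    pair <- structure_pair(switch_ref, switch_strained, partner_clash,
                           partner_strained, helix_range)
    helix_axis <- principal_axis(switch_ref[helix_range, , drop = FALSE])
    cosphi <- abs(sum(u * helix_axis))
    attr(pair, "truth") <- list(
      angle = angle, axis = u, point = point,
      sin_phi = sin(acos(min(max(cosphi, 0), 1))))
    pair
  })
}

#' Generate a cohort of strain records from a known spring model
#'
#' Draws per-design deformation geometries, computes the implied strain
#' energy `(m sin(phi) + b) theta^2`, applies multiplicative Gaussian noise,
#' and converts each strain energy back to an accelerated off-rate so the
#' records carry self-consistent kinetics (base off-rates are set at the
#' unstrained floor).
#'
#' @param m,b spring-model coefficients, kcal/mol/rad^2.
#' @param n_designs cohort size.
#' @param theta_range,phi_range uniform sampling ranges for the pivot angle
#'   and helix angle, radians.
#' @param ddg_noise multiplicative noise fraction on the strain energy.
#' @param k_base_offrate unstrained off-rate floor, s^-1.
#' @param temperature Kelvin.
#' @param seed integer seed.
#' @return Data frame of strain records (as [strain_record] rows);
#'   `attr(, "truth")` holds `m` and `b`.
#' @export
generate_strain_cohort <- function(m = 30, b = 5, n_designs = 30,
                                   theta_range = c(0.05, 0.6),
                                   phi_range = c(0.05, pi / 2),
                                   ddg_noise = 0.1,
                                   k_base_offrate = 2e-4,
                                   temperature = 298.15,
                                   seed = 1L) {
  with_seed(seed, {
    theta <- stats::runif(n_designs, theta_range[1], theta_range[2])
    phi <- stats::runif(n_designs, phi_range[1], phi_range[2])
    sin_phi <- sin(phi)
    ddg <- (m * sin_phi + b) * theta^2
    if (ddg_noise > 0)
      ddg <- ddg * (1 + stats::rnorm(n_designs, sd = ddg_noise))
    rt <- GAS_CONSTANT_KCAL * temperature
    k_off_B_AC <- k_base_offrate * exp(ddg / rt)
    records <- do.call(rbind, lapply(seq_len(n_designs), function(i)
      strain_record(sprintf("design_%02d", i), k_off_B_AC[i],
                    k_base_offrate, theta[i], sin_phi[i],
                    k_base_offrate = k_base_offrate,
                    temperature = temperature)))
    attr(records, "truth") <- list(m = m, b = b)
    records
  })
}
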