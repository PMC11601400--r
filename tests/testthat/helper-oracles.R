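# Independent oracles used across the suite.  These deliberately do not
# share code paths with the package: the ODE oracle integrates the printed
# rate equations numerically (adaptive Runge-Kutta via deSolve), and the
# superposition oracle solves the rotation by Horn's quaternion method
# rather than SVD.

# Adaptive numerical integration of the dissociation ODE system.
# Returns a matrix with columns ba, bac, ban on the requested time grid.
ode_oracle <- function(rates, effector_conc, state0 = c(ba = 1, bac = 0,
                                                        ban = 0),
                       times) {
  rhs <- function(t, y, p) {
    list(c(
      bac = -p[["k_off_B_AC"]] * y[["bac"]] +
        p[["k_on_BA_C"]] * y[["ba"]] * p[["C"]] -
        p[["k_off_BA_C"]] * y[["bac"]],
      ba = -p[["k_off_B_A"]] * y[["ba"]] -
        p[["k_on_BA_C"]] * y[["ba"]] * p[["C"]] +
        p[["k_off_BA_C"]] * y[["bac"]],
      ban = -p[["k_off_B_An"]] * y[["ban"]]))
  }
  p <- c(unclass(rates), C = effector_conc)
  out <- deSolve::ode(
    y = c(bac = unname(state0[["bac"]]), ba = unname(state0[["ba"]]),
          ban = unname(state0[["ban"]])),
    times = times, func = rhs, parms = p,
    method = "lsoda", rtol = 1e-12, atol = 1e-14)
  cbind(ba = out[, "ba"], bac = out[, "bac"], ban = out[, "ban"])
}

# Brute-force half-time: dense numerical trajectory + bisection between
# bracketing grid points.
half_time_oracle <- function(rates, effector_conc) {
  hi <- 10 * log(2) / min(c(rates[["k_off_B_A"]], rates[["k_off_B_AC"]])
                          [c(rates[["k_off_B_A"]],
                             rates[["k_off_B_AC"]]) > 0])
  repeat {
    times <- seq(0, hi, length.out = 20000)
    tr <- ode_oracle(rates, effector_conc, times = times)
    tot <- tr[, "ba"] + tr[, "bac"]
    if (min(tot) < 0.5) break
    hi <- hi * 4
  }
  i <- which(tot < 0.5)[1]
  lo_t <- times[i - 1]; hi_t <- times[i]
  f <- function(t) {
    y <- ode_oracle(rates, effector_conc, times = c(0, t))
    y[2, "ba"] + y[2, "bac"] - 0.5
  }
  stats::uniroot(f, c(lo_t, hi_t), tol = hi_t * 1e-12)$root
}

# Horn's closed-form quaternion solution for absolute orientation.
superpose_oracle <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  a <- sweep(moving, 2, cm); b <- sweep(fixed, 2, cf)
  m <- crossprod(a, b)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  n <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz),
    4, 4, byrow = TRUE)
  q <- eigen(n, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  r <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  trans <- cf - as.vector(r %*% cm)
  moved <- moving %*% t(r) + matrix(trans, nrow(moving), 3, byrow = TRUE)
  list(rotation = r, translation = trans,
       rmsd = sqrt(mean(rowSums((moved - fixed)^2))))
}

random_rigid <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  list(rotation = rotation_about_axis(ax, stats::runif(1, 0, pi)),
       translation = stats::rnorm(3, sd = 20))
}

# Random rate set on the scales the experiments probe (log-uniform).
random_rates <- function() {
  rate_constants(10^stats::runif(1, -6, 0), 10^stats::runif(1, 3, 7),
                 10^stats::runif(1, -6, 0), 10^stats::runif(1, -6, 0),
                 10^stats::runif(1, -6, 0))
}

# Random generating parameters for global-fit round trips: drawn so the
# k_eff transition lies inside the 32-fold dilution window of the default
# schedule (identifiable design; see the methods vignette).
random_identifiable_truth <- function() {
  k_off_B_A <- 10^stats::runif(1, log10(5e-4), log10(5e-3))
  ratio <- 10^stats::runif(1, log10(5), log10(25))
  k_off_B_AC <- k_off_B_A * ratio
  c_hi <- 5e-6
  k_on <- 10^stats::runif(1, log10(2), log10(6)) * k_off_B_AC / c_hi
  list(rates = rate_constants(k_off_B_A, k_on,
                              10^stats::runif(1, -4, -2), k_off_B_AC,
                              10^stats::runif(1, -6, -4)),
       response = response_model(
         a_BA = stats::runif(1, 50, 200),
         a_BAC = stats::runif(1, 50, 200),
         a_BAn = stats::runif(1, 50, 200),
         f_cycle = 1,
         f_responsive = stats::runif(1, 0.75, 0.95)))
}

rel_err <- function(est, truth) abs(est / truth - 1)

apply_rigid_pts <- function(x, tf) {
  x %*% t(tf$rotation) + matrix(tf$translation, nrow(x), 3, byrow = TRUE)
}
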