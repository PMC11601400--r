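# Closed-form curve fits: exponentials, apparent-rate laws, FP isotherm,
# baseline drift.

test_that("single exponential recovers exact decay and rise parameters", {
  t <- seq(0, 200, by = 2)
  fit <- fit_single_exponential(t, 2 + 3 * exp(-0.05 * t))
  expect_lt(rel_err(fit$s0, 2), 1e-9)
  expect_lt(rel_err(fit$s1, 3), 1e-9)
  expect_lt(rel_err(fit$k1, 0.05), 1e-9)
  expect_equal(fit$reported_k, fit$k1)

  rise <- fit_single_exponential(t, 10 + 5 * (1 - exp(-0.02 * t)),
                                 mode = "rise")
  expect_lt(rel_err(rise$s0, 10), 1e-8)
  expect_lt(rel_err(rise$s1, 5), 1e-8)
  expect_lt(rel_err(rise$k1, 0.02), 1e-8)
})

test_that("constant signals are flagged with zero amplitude", {
  t <- 0:20
  fit <- fit_single_exponential(t, rep(4.2, 21))
  expect_equal(fit$s1, 0)
  expect_true(is.na(fit$reported_k))
  expect_match(fit$flags, "unidentifiable")
})

test_that("single-exponential rate recovery survives 2% noise", {
  t <- seq(0, 400, by = 5)
  ks <- vapply(1:20, function(seed) {
    set.seed(seed)
    s <- 1 + 2 * (1 - exp(-0.01 * t)) + rnorm(length(t), sd = 0.04)
    fit_single_exponential(t, s, mode = "rise")$k1
  }, numeric(1))
  expect_lt(rel_err(stats::median(ks), 0.01), 0.05)
})

test_that("double exponential recovers both populations and reports the
           faster, higher-amplitude rate", {
  t <- seq(0, 3000, by = 5)
  s <- 1 + 0.7 * exp(-0.1 * t) + 0.3 * exp(-0.001 * t)
  fit <- fit_double_exponential(t, s)
  expect_equal(fit$n_components, 2L)
  expect_lt(rel_err(fit$k1, 0.1), 1e-6)
  expect_lt(rel_err(fit$k2, 0.001), 1e-6)
  expect_lt(rel_err(fit$s1, 0.7), 1e-6)
  expect_equal(fit$reported_k, fit$k1)
  expect_length(fit$flags, 0)
})

test_that("double exponential collapses on single-population input", {
  t <- seq(0, 500, by = 5)
  fit <- fit_double_exponential(t, 2 + 5 * exp(-0.02 * t))
  expect_equal(fit$n_components, 1L)
  expect_lt(rel_err(fit$reported_k, 0.02), 1e-6)
})

test_that("the 25% amplitude rule decides conflicted reporting", {
  t <- seq(0, 5000, by = 5)
  # faster component with 30% amplitude: faster rate reported, flagged
  s <- 1 + 0.3 * exp(-0.05 * t) + 0.7 * exp(-0.0005 * t)
  fit <- fit_double_exponential(t, s)
  expect_lt(rel_err(fit$reported_k, 0.05), 1e-4)
  expect_match(fit$flags, "lower amplitude")
  # faster component with 10% amplitude: slower, higher-amplitude rate
  s2 <- 1 + 0.1 * exp(-0.05 * t) + 0.9 * exp(-0.0005 * t)
  fit2 <- fit_double_exponential(t, s2)
  expect_lt(rel_err(fit2$reported_k, 5e-4), 1e-4)
  expect_match(fit2$flags, "below 25%")
})

test_that("fast-rate recovery holds across noisy two-population data", {
  t <- seq(0, 2000, by = 4)
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed)
    s <- 1 + 0.7 * exp(-0.05 * t) + 0.3 * exp(-0.002 * t) +
      rnorm(length(t), sd = 0.01)
    fit <- fit_double_exponential(t, s)
    if (is.finite(fit$reported_k) && rel_err(fit$reported_k, 0.05) < 0.10)
      hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("linear k_app fit is exact on exact data and guards rank", {
  concs <- c(1, 2, 4, 8, 16) * 1e-7
  pr <- kapp_profile(concs, 5e4 * concs + 1e-3)
  fit <- fit_kapp_linear(pr)
  expect_equal(unname(fit$linear[["k_on"]]), 5e4, tolerance = 1e-10)
  expect_equal(unname(fit$linear[["k_off_intercept"]]), 1e-3,
               tolerance = 1e-10)
  expect_error(fit_kapp_linear(kapp_profile(rep(1e-7, 5), 1:5 * 1e-3)),
               "distinct")
})

test_that("linear k_app slope recovery under 5% noise", {
  concs <- 1e-7 * 2^(0:7)
  slopes <- vapply(1:20, function(seed) {
    set.seed(seed)
    k <- 5e4 * concs + 1e-3
    pr <- kapp_profile(concs, k + rnorm(8, sd = 0.05 * max(k)))
    unname(fit_kapp_linear(pr)$linear[["k_on"]])
  }, numeric(1))
  expect_lt(rel_err(stats::median(slopes), 5e4), 0.10)
})

test_that("hyperbolic k_app fit recovers exact parameters and limits", {
  concs <- 2e-7 * 2^(-3:4)
  truth <- list(k_switch = 0.02, k_base = 1e-4, K_half = 2e-7)
  k <- (truth$k_switch - truth$k_base) * concs / (truth$K_half + concs) +
    truth$k_base
  fit <- fit_kapp_hyperbolic(kapp_profile(concs, k))
  h <- fit$hyperbolic
  expect_lt(rel_err(h[["k_switch"]], 0.02), 1e-6)
  expect_lt(rel_err(h[["k_base"]], 1e-4), 1e-6)
  expect_lt(rel_err(h[["K_half"]], 2e-7), 1e-6)
  # intercept identity and saturation of the fitted curve
  expect_equal(unname(predict(fit, 0)), unname(h[["k_base"]]))
  expect_lt(rel_err(predict(fit, 100 * h[["K_half"]]), h[["k_switch"]]),
            0.01)
})

test_that("mechanism discrimination selects the generating law", {
  concs <- 2e-7 * 2^(-3:4)
  lin <- generate_kapp_profile("induced_fit",
                               list(k_on = 5e4, k_off = 1e-3), concs,
                               noise_spec(sd = 0, seed = 1))
  expect_equal(discriminate_mechanism(lin)$model, "linear")
  hyp <- generate_kapp_profile(
    "conformational_selection",
    list(k_switch = 0.02, k_base = 1e-4, K_half = 2e-7), concs,
    noise_spec(sd = 0, seed = 1))
  expect_equal(discriminate_mechanism(hyp)$model, "hyperbolic")
  expect_error(discriminate_mechanism(kapp_profile(c(1e-7, 2e-7),
                                                   c(1e-3, 2e-3))),
               "distinct")
})

test_that("AIC-based selection is invariant to rate-unit rescaling", {
  concs <- 2e-7 * 2^(-3:4)
  set.seed(3)
  pr <- generate_kapp_profile(
    "conformational_selection",
    list(k_switch = 0.02, k_base = 1e-4, K_half = 2e-7), concs,
    noise_spec(sd = 0.05, seed = 3))
  f1 <- discriminate_mechanism(pr)
  pr_min <- kapp_profile(pr$concs, pr$kapps * 60)   # per-minute units
  f2 <- discriminate_mechanism(pr_min)
  expect_equal(f1$model, f2$model)
  expect_equal(f1$aic_linear - f1$aic_hyperbolic,
               f2$aic_linear - f2$aic_hyperbolic, tolerance = 1e-8)
})

test_that("polarization follows the printed intensity formula", {
  expect_equal(polarization(1, 1), 0)
  expect_equal(polarization(2, 0), 1000)
  expect_equal(polarization(2, 1), 1000 / 3)
  expect_error(polarization(0, 0), "positive")
})

test_that("bound fraction matches closed form and equilibrium mass balance", {
  expect_equal(bound_fraction(0, 1e-9, 1e-8), 0)
  # stoichiometric limit: kd -> 0 with host >= effector
  expect_equal(bound_fraction(1e-8, 1e-9, 0), 1)
  # equal host, effector, kd = K: f = (3 - sqrt(5))/2
  for (K in c(1e-9, 1e-6)) {
    f <- bound_fraction(K, K, K)
    expect_equal(f, (3 - sqrt(5)) / 2, tolerance = 1e-12)
    # cross-check by solving the mass balance numerically:
    # f*C complexed; free host A - fC; free effector C(1-f);
    # K = freeA*freeC/complex
    g <- function(f) (K - f * K) * (K - f * K) / (f * K) - K
    f_num <- stats::uniroot(g, c(1e-12, 1 - 1e-12), tol = 1e-15)$root
    expect_equal(f, f_num, tolerance = 1e-9)
  }
  # monotonicity in host and kd; bounded in [0, 1]
  a <- 10^seq(-12, -5, length.out = 40)
  f_a <- bound_fraction(a, 1e-9, 1e-8)
  expect_true(all(diff(f_a) > 0) && all(f_a >= 0 & f_a <= 1))
  f_k <- vapply(10^seq(-10, -6, length.out = 20),
                function(k) bound_fraction(1e-8, 1e-9, k), numeric(1))
  expect_true(all(diff(f_k) < 0))
})

test_that("isotherm fit recovers exact parameters and applies censoring", {
  a <- 1e-6 / 2^(0:23)
  p <- 50 + 150 * bound_fraction(a, 1e-10, 1e-8)
  fit <- fit_isotherm(a, p, 1e-10)
  expect_lt(rel_err(fit$p0, 50), 1e-7)
  expect_lt(rel_err(fit$p1, 150), 1e-7)
  expect_lt(rel_err(fit$kd, 1e-8), 1e-6)
  expect_false(fit$censored)

  # affinity tighter than the probe concentration: censored as K_D < [C]
  cens <- fit_isotherm(a, 50 + 150 * bound_fraction(a, 1e-9, 1e-10), 1e-9)
  expect_true(cens$censored)
  expect_equal(cens$kd, 1e-9)
})

test_that("K_D recovery on the 24-well titration design under 2% noise", {
  kds <- vapply(1:20, function(seed) {
    ti <- generate_fp_titration(kd = 1e-8, effector_conc = 1e-10,
                                noise = noise_spec(sd = 0.02, seed = seed))
    fit_isotherm(ti$host_conc_M, ti$polarization_mP, 1e-10)$kd
  }, numeric(1))
  expect_lt(rel_err(stats::median(kds), 1e-8), 0.15)
})

test_that("competition time course behaves as a rise exponential", {
  t <- seq(0, 600, by = 5)
  p <- 60 + 120 * (1 - exp(-0.008 * t))
  fit <- fit_competition_timecourse(t, p)
  expect_lt(rel_err(fit$k1, 0.008), 1e-8)
  expect_equal(fit$mode, "rise")
})

test_that("baseline drift fit recovers the sigmoid and subtracts cleanly", {
  t <- seq(0, 1200, by = 10)
  s <- 1 + 0.2 / (1 + exp(-0.01 * (t - 300)))
  fit <- fit_baseline_drift(t, s)
  expect_lt(rel_err(fit$s0, 1), 1e-7)
  expect_lt(rel_err(fit$s1, 0.2), 1e-7)
  expect_lt(rel_err(fit$k, 0.01), 1e-6)
  expect_lt(rel_err(fit$t_half, 300), 1e-6)

  flat <- fit_baseline_drift(t, rep(2, length(t)))
  expect_equal(flat$s1, 0)
  expect_match(flat$flags, "no drift")

  # drift-contaminated decay: subtracting the fitted drift restores the rate
  decay <- 3 * exp(-0.02 * t)
  drift <- 0.3 / (1 + exp(-0.008 * (t - 500))) + 0.5
  base_fit <- fit_baseline_drift(t, drift)
  clean <- subtract_drift(base_fit, t, decay + drift)
  k_rec <- fit_single_exponential(t, clean)$k1
  expect_lt(rel_err(k_rec, 0.02), 0.05)
})
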