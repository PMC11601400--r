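# Multi-cycle experiment: initial-value recursion, simulation, global fit.

test_that("cycle recursion base cases follow the printed boundary rules", {
  r <- rate_constants(2e-3, 3e4, 1e-3, 0.05, 1e-5)
  sch1 <- cycle_schedule(5e-6)
  st <- cycle_initial_states(r, sch1, f_responsive = 1)[[1]]
  expect_equal(unname(st[c("ba", "bac", "ban")]), c(1, 0, 0))

  # f_responsive = 0: all refill goes to the unresponsive pool
  sch2 <- cycle_schedule(c(5e-6, 2.5e-6))
  sts <- cycle_initial_states(r, sch2, f_responsive = 0)
  expect_equal(unname(sts[[1]][c("ba", "ban")]), c(0, 1))
  expect_error(cycle_initial_states(r, sch2, f_responsive = 1.2), "0, 1")
})

test_that("cycle initial states match a hand-stepped recursion on ODE finals", {
  skip_if_not_installed("deSolve")
  r <- rate_constants(1e-4, 1e5, 1e-3, 0.1, 1e-5)
  sch <- cycle_schedule(5e-6 / 2^(0:5), dissociation_window = 600)
  fr <- 0.9
  got <- cycle_initial_states(r, sch, f_responsive = fr)

  ba_f <- 0; ban_f <- 0
  for (n in 1:6) {
    b_f <- 1 - ba_f - ban_f
    ba0 <- ba_f + fr * b_f
    ban0 <- ban_f + (1 - fr) * b_f
    expect_equal(unname(got[[n]][["ba"]]), ba0, tolerance = 1e-7)
    expect_equal(unname(got[[n]][["bac"]]), 0)
    expect_equal(unname(got[[n]][["ban"]]), ban0, tolerance = 1e-7)
    fin <- ode_oracle(r, sch$effector_concs[n],
                      c(ba = ba0, bac = 0, ban = ban0), c(0, 600))[2, ]
    ba_f <- fin[["ba"]] + fin[["bac"]]   # terminal ternary folds into BA
    ban_f <- fin[["ban"]]
  }
})

test_that("unresponsive host accumulates across cycles iff f_responsive < 1", {
  r <- rate_constants(2e-3, 3e4, 1e-3, 0.05, 1e-5)
  sch <- cycle_schedule(5e-6 / 2^(0:5))
  ban0 <- vapply(cycle_initial_states(r, sch, 0.85),
                 function(s) s[["ban"]], numeric(1))
  expect_true(all(diff(ban0) > 0))
  ban1 <- vapply(cycle_initial_states(r, sch, 1),
                 function(s) s[["ban"]], numeric(1))
  expect_equal(ban1, rep(0, 6))
})

test_that("simulated responses are amplitude-weighted occupancies", {
  r <- rate_constants(2e-3, 3e4, 1e-3, 0.05, 1e-5)
  sch <- cycle_schedule(c(0, 0), dissociation_window = 100)
  ds <- simulate_cycles(r, sch, response_model(a_BA = 1, a_BAC = 1,
                                               a_BAn = 1))
  # cycle 1, no effector: pure base-rate exponential
  expect_equal(ds$cycles[[1]]$response_RU,
               exp(-2e-3 * ds$cycles[[1]]$time_s), tolerance = 1e-12)

  # homogeneity: doubling all amplitudes doubles every response
  sch2 <- cycle_schedule(5e-6 / 2^(0:2))
  d1 <- simulate_cycles(r, sch2, response_model(a_BA = 50, a_BAC = 60,
                                                a_BAn = 70,
                                                f_responsive = 0.9))
  d2 <- simulate_cycles(r, sch2, response_model(a_BA = 100, a_BAC = 120,
                                                a_BAn = 140,
                                                f_responsive = 0.9))
  for (n in 1:3)
    expect_equal(d2$cycles[[n]]$response_RU,
                 2 * d1$cycles[[n]]$response_RU, tolerance = 1e-12)

  # composition with an independently computed occupancy propagation
  inits <- cycle_initial_states(r, sch2, 0.9)
  tr <- propagate_dissociation(r, sch2$effector_concs[2], inits[[2]],
                               d1$cycles[[2]]$time_s)
  expect_equal(d1$cycles[[2]]$response_RU,
               50 * tr$states[, "ba"] + 60 * tr$states[, "bac"] +
                 70 * tr$states[, "ban"], tolerance = 1e-12)
})

test_that("the amplitude/scale gauge is resolved by pinning f_1 = 1", {
  # multiplying amplitudes by c and dividing f_n by c leaves the response
  # unchanged only when the first factor can drift; the constructor pins it
  expect_error(response_model(a_BA = 100, f_cycle = c(2, 1)), "gauge")
  r <- rate_constants(2e-3, 3e4, 1e-3, 0.05, 1e-5)
  sch <- cycle_schedule(5e-6 / 2^(0:1))
  base <- simulate_cycles(r, sch, response_model(a_BA = 100,
                                                 f_cycle = c(1, 0.5)))
  scaled <- simulate_cycles(r, sch, response_model(a_BA = 50,
                                                   f_cycle = c(1, 1)))
  expect_equal(base$cycles[[2]]$response_RU,
               scaled$cycles[[2]]$response_RU, tolerance = 1e-12)
})

test_that("global fit is self-consistent on noise-free data", {
  truth <- rate_constants(2e-3, 3e4, 1e-3, 0.05, 1e-5)
  resp <- response_model(a_BA = 100, a_BAC = 110, a_BAn = 90,
                         f_responsive = 0.9)
  ds <- simulate_cycles(truth, cycle_schedule(5e-6 / 2^(0:5)), resp)
  fit <- fit_global(ds, init = c(as.list(unclass(truth)),
                                 list(a_BA = 100, a_BAC = 110, a_BAn = 90,
                                      f_responsive = 0.9)),
                    n_starts = 1)
  expect_lt(rel_err(fit$rates[["k_off_B_A"]], 2e-3), 1e-6)
  expect_lt(rel_err(fit$rates[["k_off_B_AC"]], 0.05), 1e-6)
  expect_lt(abs(fit$response$f_responsive - 0.9), 1e-6)
  expect_lt(fit$residual_sse, 1e-12)
  expect_equal(fit$residual_sse, sum(fit$per_cycle_residuals))
})

test_that("global fit recovers parameters from noisy data", {
  truth <- rate_constants(2e-3, 3e4, 1e-3, 0.05, 1e-5)
  resp <- response_model(a_BA = 100, f_responsive = 0.9)
  ds <- generate_spr_dataset(truth, cycle_schedule(5e-6 / 2^(0:5)), resp,
                             noise_spec(sd = 0.01, seed = 101))
  set.seed(1)
  fit <- fit_global(ds)
  expect_lt(rel_err(fit$rates[["k_off_B_A"]], 2e-3), 0.10)
  expect_lt(rel_err(fit$rates[["k_off_B_AC"]], 0.05), 0.10)
  expect_lt(abs(fit$response$f_responsive - 0.9), 0.05)
})

test_that("noise-free round trip recovers random truths from off inits", {
  set.seed(2024)
  n_ok <- 0
  for (i in 1:10) {
    tr <- random_identifiable_truth()
    ds <- simulate_cycles(tr$rates, cycle_schedule(5e-6 / 2^(0:5)),
                          tr$response)
    init <- c(as.list(unclass(tr$rates)),
              list(a_BA = tr$response$a_BA, a_BAC = tr$response$a_BAC,
                   a_BAn = tr$response$a_BAn,
                   f_responsive = tr$response$f_responsive))
    # perturb every start value by x3 or /3 (amplitude-ish for f_responsive)
    for (nm in names(init)) {
      if (nm == "f_responsive")
        init[[nm]] <- min(max(init[[nm]] + sample(c(-0.1, 0.1), 1), 0.05),
                          0.95)
      else init[[nm]] <- init[[nm]] * sample(c(3, 1 / 3), 1)
    }
    fit <- fit_global(ds, init = init, n_starts = 4)
    ok <- rel_err(fit$rates[["k_off_B_A"]],
                  tr$rates[["k_off_B_A"]]) < 1e-4 &&
      rel_err(fit$rates[["k_off_B_AC"]], tr$rates[["k_off_B_AC"]]) < 1e-4 &&
      abs(fit$response$f_responsive - tr$response$f_responsive) < 1e-4
    n_ok <- n_ok + ok
  }
  expect_equal(n_ok, 10)
})

test_that("k_eff is insensitive to the covarying effector on/off pair", {
  # with k_on [C] >> partner off-rates, scaling (k_on, k_off,BA:C) jointly
  # leaves the dissociation kinetics unchanged -> the pair is flagged
  truth <- rate_constants(2e-3, 1e7, 1e-3, 0.05, 1e-5)
  concs <- 5e-6 / 2^(0:5)
  k1 <- effective_rate(truth, concs)
  perturbed <- rate_constants(2e-3, 1e8, 1e-2, 0.05, 1e-5)
  k2 <- effective_rate(perturbed, concs)
  expect_lt(max(rel_err(k2, k1)), 0.05)

  ds <- simulate_cycles(truth, cycle_schedule(concs),
                        response_model(a_BA = 100, f_responsive = 0.9))
  fit <- fit_global(ds, init = c(as.list(unclass(truth)),
                                 list(a_BA = 100, f_responsive = 0.9)),
                    n_starts = 1)
  expect_true(any(grepl("covary", fit$covariance_flags)))
})

test_that("unidentifiable designs are refused and fold change is guarded", {
  r <- rate_constants(2e-3, 3e4, 1e-3, 0.05, 1e-5)
  ds1 <- simulate_cycles(r, cycle_schedule(5e-6),
                         response_model(a_BA = 100))
  expect_error(fit_global(ds1), ">= 2 cycles")
  ds0 <- simulate_cycles(r, cycle_schedule(c(0, 0)),
                         response_model(a_BA = 100))
  expect_error(fit_global(ds0), "zero effector")

  expect_equal(fold_change(rate_constants(0.05, 3e4, 1e-3, 0.05)), 1)
  expect_equal(fold_change(r), 25)
  expect_error(fold_change(rate_constants(0, 3e4, 1e-3, 0.05)),
               "undefined")
})
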