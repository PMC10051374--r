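# Cooling-regime estimation: tau_s fitting, hS inversion, Q0, and the
# energy-balance conversion efficiency.

test_that("fit_cooling recovers tau exactly on noise-free data", {
  tr <- analytic_cooling_trace(tau = 237)
  fit <- fit_cooling(tr)
  expect_equal(fit$tau_s, 237, tolerance = 1e-6)
  expect_equal(fit$T_env_hat, 25)
  expect_equal(fit$T_max_hat, 55)
  expect_gte(fit$n_points, 5)
  expect_lt(fit$rmse, 1e-6)
})

test_that("fit_cooling recovers tau = 248 s within 3% under camera noise", {
  cfg0 <- synth_experiment_config(true_eta = 0.30, heat_duration = 1500,
                                  seed = 1)
  sys <- thermal_system(cfg0$components, heat_loss = cfg0$hS, ambient = 25)
  expect_equal(relaxation_time(sys), 248)
  taus <- vapply(1:5, function(s) {
    e <- gen_experiment(synth_experiment_config(true_eta = 0.30, seed = s))
    fit_cooling(e$sample_trace)$tau_s
  }, numeric(1))
  expect_true(all(abs(taus / 248 - 1) < 0.03))
})

test_that("fit_cooling rejects degenerate and truncated inputs", {
  flat <- analytic_cooling_trace(tau = 237, T_max = 25.05)
  expect_error(fit_cooling(flat), class = "pttdose_insufficient_signal")
  no_off <- temperature_trace(0:100, rep(30, 101))
  expect_error(fit_cooling(no_off), class = "pttdose_error")
  short <- analytic_cooling_trace(tau = 237, cool = 7)
  expect_error(fit_cooling(short), class = "pttdose_insufficient_data")
})

test_that("infer_hS inverts the relaxation-time relation", {
  sys <- water_system(hS = 8.83e-3)
  expect_equal(infer_hS(237, sys), 2.093 / 237, tolerance = 1e-12)
  expect_equal(infer_hS(237, sys), 8.83e-3, tolerance = 1e-3)
  # round trip: tau from the system's own hS returns that hS
  expect_equal(infer_hS(relaxation_time(sys), sys), 8.83e-3)
  # algebraic identity: hS * tau = total heat capacity
  expect_equal(infer_hS(312.7, sys) * 312.7, total_heat_capacity(sys))
  expect_error(infer_hS(0, sys), class = "pttdose_error")
})

test_that("estimate_q0 recovers the blank's nonspecific power", {
  q0 <- vapply(1:5, function(s) {
    e <- gen_experiment(synth_experiment_config(true_eta = 0.3, seed = s))
    cfg <- synth_experiment_config(true_eta = 0.3, seed = s)
    sys <- thermal_system(cfg$components, heat_loss = cfg$hS, ambient = 25)
    estimate_q0(e$blank_trace, sys)
  }, numeric(1))
  expect_true(all(abs(q0 / 0.03 - 1) < 0.10))
})

test_that("a blank that never heats yields Q0 = 0", {
  cfg <- synth_experiment_config(true_eta = 0, Q0 = 0, noise_sd = 0, seed = 1)
  e <- gen_experiment(cfg)
  sys <- thermal_system(cfg$components, heat_loss = cfg$hS, ambient = 25)
  expect_equal(estimate_q0(e$blank_trace, sys), 0)
})

test_that("estimate_q0 rejects a blank still rising at laser-off", {
  cfg <- synth_experiment_config(true_eta = 0, Q0 = 0.03, noise_sd = 0,
                                 heat_duration = 120, seed = 1)
  e <- gen_experiment(cfg)
  sys <- thermal_system(cfg$components, heat_loss = cfg$hS, ambient = 25)
  expect_error(estimate_q0(e$blank_trace, sys),
               class = "pttdose_nonstationary")
})

test_that("absorbance dilution correction is linear with a linearity warning", {
  expect_equal(correct_absorbance(0.8, 1), 0.8)
  expect_equal(correct_absorbance(0.5, 2), 1.0)
  expect_warning(out <- correct_absorbance(1.2, 1), "linear range")
  expect_equal(out, 1.2)
  expect_error(correct_absorbance(0.5, 0.5), class = "pttdose_error")
})

test_that("compute_pce evaluates the energy balance", {
  res <- compute_pce(T_max = 55, T_env = 25, Q0 = 0.03, P = 1, A_lambda = 1,
                     hS = 0.01)
  expect_equal(res$eta, (0.01 * 30 - 0.03) / (1 * (1 - 0.1)))
  expect_equal(res$eta, 0.30, tolerance = 1e-12)
  expect_true(res$in_range)
  # blank heats as much as the sample: eta = 0
  null <- compute_pce(55, 25, Q0 = 0.3, P = 1, A_lambda = 1, hS = 0.01)
  expect_equal(null$eta, 0)
  expect_error(compute_pce(55, 25, 0.03, 1, A_lambda = 0, hS = 0.01),
               class = "pttdose_degenerate_input")
  expect_warning(bad <- compute_pce(80, 25, 0, P = 0.1, A_lambda = 1,
                                    hS = 0.01), "outside")
  expect_false(bad$in_range)
})

test_that("compute_pce on the simulator's exact steady state returns eta", {
  for (eta in c(0.17, 0.3, 0.34)) {
    hS <- 0.009
    T_max <- 25 + (eta * 0.965 * (1 - 10^-1) + 0.03) / hS
    res <- compute_pce(T_max, 25, Q0 = 0.03, P = 0.965, A_lambda = 1, hS = hS)
    expect_equal(res$eta, eta, tolerance = 1e-9)
  }
})

test_that("estimated eta increases strictly with the observed T_max", {
  etas <- vapply(seq(40, 60, by = 5), function(Tm) {
    compute_pce(Tm, 25, 0.03, 0.965, 1, 0.009)$eta
  }, numeric(1))
  expect_true(all(diff(etas) > 0))
})

test_that("full experiment chain recovers eta across a grid (bias and SD)", {
  sys <- NULL
  for (eta in c(0.1, 0.2, 0.3, 0.4, 0.5)) {
    est <- vapply(1:20, function(s) {
      cfg <- synth_experiment_config(true_eta = eta, seed = s)
      if (is.null(sys)) {
        sys <<- thermal_system(cfg$components, heat_loss = cfg$hS,
                               ambient = 25)
      }
      e <- gen_experiment(cfg)
      estimate_pce_experiment(e$sample_trace, e$blank_trace, sys,
                              P = cfg$P, A_lambda = cfg$A_lambda)$eta
    }, numeric(1))
    expect_lt(abs(mean(est) - eta), 0.01)
    expect_lt(stats::sd(est), 0.02)
  }
})

test_that("identical sample and blank give eta near zero", {
  cfg <- synth_experiment_config(true_eta = 0, noise_sd = 0, seed = 3)
  e <- gen_experiment(cfg)
  sys <- thermal_system(cfg$components, heat_loss = cfg$hS, ambient = 25)
  res <- suppressWarnings(
    estimate_pce_experiment(e$blank_trace, e$blank_trace, sys,
                            P = cfg$P, A_lambda = cfg$A_lambda))
  expect_equal(res$eta, 0, tolerance = 1e-6)
})

test_that("stage failures are reported with the failing stage", {
  cfg <- synth_experiment_config(true_eta = 0.3, noise_sd = 0, seed = 1)
  e <- gen_experiment(cfg)
  sys <- thermal_system(cfg$components, heat_loss = cfg$hS, ambient = 25)
  no_tail <- temperature_trace(e$sample_trace$times, e$sample_trace$temps,
                               power = e$sample_trace$power)
  expect_error(
    estimate_pce_experiment(no_tail, e$blank_trace, sys, P = cfg$P,
                            A_lambda = cfg$A_lambda),
    "steady-state check|fit_cooling")
})
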