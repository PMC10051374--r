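# Lumped-capacitance model: heat capacity, relaxation time, dimensionless
# temperature, exact exponential simulation, and the capped-session
# controller.

test_that("total heat capacity sums m*cp and rejects invalid components", {
  sys <- water_system()
  expect_equal(total_heat_capacity(sys), 2.093)
  two <- thermal_system(list(thermal_component("water", 0.5, 4.186),
                             thermal_component("water2", 0.5, 4.186)))
  expect_equal(total_heat_capacity(two), 2 * 2.093)
  expect_error(thermal_component("x", 0, 4.186), class = "pttdose_error")
  expect_error(thermal_system(list()), class = "pttdose_error")
})

test_that("relaxation time is heat capacity over hS", {
  sys <- water_system(hS = 8.83e-3)
  expect_equal(relaxation_time(sys), 2.093 / 8.83e-3, tolerance = 1e-12)
  expect_equal(relaxation_time(sys), 237.0, tolerance = 1e-3)
  sys2 <- water_system(hS = 2 * 8.83e-3)
  expect_equal(relaxation_time(sys2), relaxation_time(sys) / 2)
  expect_error(relaxation_time(water_system(hS = NA)),
               class = "pttdose_error")
})

test_that("dimensionless temperature maps ambient to 0 and maximum to 1", {
  tr <- temperature_trace(0:2, c(55, 25, 40))
  th <- dimensionless_theta(tr, T_env = 25, T_max = 55)
  expect_equal(th$theta, c(1, 0, 0.5))
  expect_error(dimensionless_theta(tr, 25, 25),
               class = "pttdose_degenerate_input")
})

test_that("zero laser power holds the system at ambient", {
  tr <- simulate_trace(water_system(), optical_sample(1, 0.3),
                       laser_source(0), duration = 100, dt = 1)
  expect_equal(tr$temps, rep(25, 101))
})

test_that("steady-state rise equals (eta*P*(1-10^-A) + Q0)/hS", {
  sys <- water_system(hS = 0.01)
  samp <- optical_sample(absorbance = 1, pce = 0.3, baseline_power = 0.03)
  tr <- simulate_trace(sys, samp, laser_source(1), duration = 4000, dt = 1)
  expect_equal(max(tr$temps) - 25, 30, tolerance = 1e-3)
})

test_that("simulation matches the closed form exactly at any step size", {
  sys <- water_system(hS = 0.01) # tau = 209.3 s
  samp <- optical_sample(1, 0.3, baseline_power = 0.03)
  tau <- relaxation_time(sys)
  T_ss <- 25 + 30
  for (dt in c(0.5, 7)) {
    tr <- simulate_trace(sys, samp, laser_source(1), duration = 1400, dt = dt)
    expected <- T_ss + (25 - T_ss) * exp(-tr$times / tau)
    expect_lt(max(abs(tr$temps - expected)), 1e-9)
  }
})

test_that("noise-free cooling gives Theta(t) = exp(-t/tau), Theta(tau)=1/e", {
  sys <- water_system(hS = 2.093 / 200) # tau exactly 200 s
  samp <- optical_sample(1, 0.3, baseline_power = 0.03)
  laser <- laser_source(1, schedule = data.frame(start = 0, end = 3000,
                                                 power = 1))
  tr <- simulate_trace(sys, samp, laser, duration = 3800, dt = 1)
  expect_equal(tr$t_off, 3000)
  T_max <- tr$temps[tr$times == 3000]
  tail_idx <- tr$times >= 3000
  th <- (25 - tr$temps[tail_idx]) / (25 - T_max)
  tc <- tr$times[tail_idx] - 3000
  expect_lt(max(abs(th - exp(-tc / 200))), 1e-9)
  expect_equal(th[tc == 200], exp(-1), tolerance = 1e-9)
  expect_true(all(diff(th) < 0))
})

test_that("photobleaching makes the heating curve peak and then decline", {
  sys <- water_system(hS = 2.093 / 248)
  samp <- optical_sample(1, 0.34, baseline_power = 0.03, bleach_rate = 2e-3)
  laser <- laser_source(0.965, schedule = data.frame(start = 0, end = 900,
                                                     power = 0.965))
  tr <- simulate_trace(sys, samp, laser, duration = 1000, dt = 1)
  on <- tr$times <= 900
  peak <- which.max(tr$temps[on])
  expect_lt(peak, 0.8 * sum(on))
  expect_lt(tr$temps[sum(on)], max(tr$temps[on]))
})

test_that("traces are bit-identical for identical seeds", {
  sys <- water_system()
  samp <- optical_sample(1, 0.3)
  a <- simulate_trace(sys, samp, laser_source(1), 500, 1, noise_sd = 0.2,
                      seed = 7)
  b <- simulate_trace(sys, samp, laser_source(1), 500, 1, noise_sd = 0.2,
                      seed = 7)
  c <- simulate_trace(sys, samp, laser_source(1), 500, 1, noise_sd = 0.2,
                      seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$temps, c$temps))
})

test_that("controller stays inactive when the threshold is never reached", {
  sys <- water_system(hS = 0.01, ambient = 25)
  samp <- optical_sample(1, 0.1) # plateau 34 C
  tr <- simulate_session(sys, samp, laser_source(1), 2000, 1, threshold = 55)
  expect_equal(tr$power, rep(1, length(tr$times)))
})

test_that("capped sessions respect the one-step overshoot bound", {
  sys <- thermal_system(list(thermal_component("tumor", 0.12, 3.5)),
                        heat_loss = 0.015, ambient = 32.5) # tau = 28 s
  tau <- relaxation_time(sys)
  for (eta in c(0.45, 0.6, 0.9)) {
    samp <- optical_sample(1, eta)
    T_ss_max <- 32.5 + eta * 0.965 * 0.9 / 0.015
    dt <- 0.1
    tr <- simulate_session(sys, samp, laser_source(0.965), 600, dt,
                           threshold = 55, step_down = 0.1)
    bound <- 55 + (dt / tau) * (T_ss_max - 55)
    expect_lte(max(tr$temps), bound)
    expect_true(all(diff(tr$power) <= 1e-12))
  }
})

test_that("near-total power cuts drive the session back toward ambient", {
  sys <- thermal_system(list(thermal_component("tumor", 0.12, 3.5)),
                        heat_loss = 0.015, ambient = 32.5)
  samp <- optical_sample(1, 0.9)
  tr <- simulate_session(sys, samp, laser_source(0.965), 900, 1,
                         threshold = 55, step_down = 0.99)
  expect_lt(tr$temps[length(tr$temps)], 34)
  expect_error(simulate_session(sys, samp, laser_source(0.965), 900, 1,
                                threshold = 30), class = "pttdose_error")
})

test_that("simulation rejects nonpositive step sizes", {
  expect_error(simulate_trace(water_system(), optical_sample(1, 0.3),
                              laser_source(1), 100, 0),
               class = "pttdose_error")
})
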