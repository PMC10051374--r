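#' Simulate laser heating and cooling of a lumped system
#'
#' Forward model of the sample temperature under a scheduled laser power.
#' Within each constant-power interval the temperature follows the exact
#' exponential solution of the lumped energy balance,
#' `T(t + dt) = T_ss + (T(t) - T_ss) * exp(-dt / tau_s)`, with steady state
#' `T_ss = T_env + (eta * P * (1 - 10^-A) + Q0 * P / P_nom) / hS`. The
#' per-segment update is exact, so the noise-free trace carries no
#' discretization error at any step size. With a positive `bleach_rate` the
#' specific absorbed term decays as `exp(-bleach_rate * t_on)` with
#' accumulated laser-on time (first-order photobleaching). Gaussian
#' measurement noise is added to the noise-free solution.
#'
#' The nonspecific absorbed power Q0 is referred to the nominal laser power
#' and scales proportionally when the applied power differs from nominal; it
#' vanishes when the laser is off.
#'
#' @param system A [thermal_system()] with `heat_loss` set.
#' @param sample An [optical_sample()].
#' @param laser A [laser_source()].
#' @param duration Record length in seconds.
#' @param dt Sampling interval in seconds, > 0.
#' @param noise_sd Standard deviation of additive Gaussian measurement noise
#'   in degrees C (0 = noise-free).
#' @param seed Optional integer seed; identical inputs and seed give
#'   bit-identical traces. `NULL` uses (and advances) the current RNG stream.
#' @param T0 Initial temperature in degrees C; defaults to ambient.
#' @return A [temperature_trace()] with the applied power recorded per sample
#'   and `t_off` set when the record contains a laser-off tail.
#' @examples
#' sys <- thermal_system(list(thermal_component("water", 0.5, 4.186)),
#'                       heat_loss = 0.01, ambient = 25)
#' samp <- optical_sample(absorbance = 1, pce = 0.3, baseline_power = 0.03)
#' tr <- simulate_trace(sys, samp, laser_source(1), duration = 2000, dt = 1)
#' max(tr$temps) - 25 # approaches 30 K steady-state rise
#' @export
simulate_trace <- function(system, sample, laser, duration, dt,
                           noise_sd = 0, seed = NULL, T0 = NULL) {
  sim_core(system, sample, laser, duration, dt, noise_sd, seed, T0,
           threshold = NULL, step_down = NULL)
}

#' Simulate a temperature-capped PTT session
#'
#' Identical to [simulate_trace()] except for a feedback power controller
#' emulating the clinical practice of tuning the laser power down when the
#' monitored temperature reaches a safety threshold (55 degrees C by
#' default). Whenever the current (noise-free) temperature is at or above
#' `threshold`, the applied power is attenuated by the factor
#' `(1 - step_down)`, repeatedly within the control step until the implied
#' steady-state temperature is at or below the threshold. Power is never
#' restored, so the applied power trace is monotone non-increasing; as a
#' consequence the noise-free temperature can exceed the threshold by at most
#' the one-step rise bound `(dt / tau_s) * (T_ss_max - threshold)`.
#'
#' @inheritParams simulate_trace
#' @param threshold Controller threshold in degrees C; must exceed ambient.
#' @param step_down Fractional power reduction per control action, in (0, 1).
#' @return A [temperature_trace()] whose `power` field records the applied
#'   (controller-attenuated) power at every sample.
#' @export
simulate_session <- function(system, sample, laser, duration, dt,
                             threshold = 55, step_down = 0.1,
                             noise_sd = 0, seed = NULL, T0 = NULL) {
  check_number(threshold, "threshold")
  if (threshold <= system$ambient) {
    ptt_error("`threshold` must exceed the ambient temperature")
  }
  check_number(step_down, "step_down")
  if (step_down <= 0 || step_down >= 1) {
    ptt_error("`step_down` must lie strictly between 0 and 1")
  }
  sim_core(system, sample, laser, duration, dt, noise_sd, seed, T0,
           threshold = threshold, step_down = step_down)
}

sim_core <- function(system, sample, laser, duration, dt, noise_sd, seed, T0,
                     threshold, step_down) {
  if (!inherits(system, "thermal_system")) {
    ptt_error("`system` must be a thermal_system")
  }
  if (!inherits(sample, "optical_sample")) {
    ptt_error("`sample` must be an optical_sample")
  }
  if (!inherits(laser, "laser_source")) {
    ptt_error("`laser` must be a laser_source")
  }
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(duration, "duration", lower = dt)
  check_number(noise_sd, "noise_sd", lower = 0)

  tau <- relaxation_time(system)
  hS <- system$heat_loss
  T_env <- system$ambient
  attn <- 1 - 10^(-sample$absorbance)
  P_nom <- laser$power
  q0_frac <- if (P_nom > 0) sample$baseline_power / P_nom else 0

  times <- seq(0, duration, by = dt)
  n <- length(times)
  Pvec <- power_at(laser, times)
  temps <- numeric(n)
  temps[1L] <- T0 %||% T_env
  applied <- Pvec
  decay <- exp(-dt / tau)

  controlled <- !is.null(threshold)
  bleaching <- sample$bleach_rate > 0

  if (!controlled && !bleaching) {
    # vectorized exact solution over runs of constant power
    runs <- rle(Pvec[-n])
    pos <- 1L
    for (k in seq_along(runs$lengths)) {
      len <- runs$lengths[k]
      P <- runs$values[k]
      T_ss <- T_env + (sample$pce * P * attn + q0_frac * P) / hS
      tt <- seq_len(len) * dt
      temps[pos + seq_len(len)] <-
        T_ss + (temps[pos] - T_ss) * exp(-tt / tau)
      pos <- pos + len
    }
  } else {
    scale <- 1
    t_on <- 0
    for (i in seq_len(n - 1L)) {
      P_sched <- Pvec[i]
      if (controlled && temps[i] >= threshold && P_sched > 0) {
        # attenuate until the implied steady state is capped at threshold;
        # no further cuts while the temperature relaxes back down
        repeat {
          bleach_fac <- if (bleaching) {
            exp(-sample$bleach_rate * t_on)
          } else 1
          T_ss_try <- T_env + scale * P_sched *
            (sample$pce * attn * bleach_fac + q0_frac) / hS
          if (T_ss_try <= threshold || scale < 1e-12) break
          scale <- scale * (1 - step_down)
        }
      }
      P_i <- if (controlled) scale * P_sched else P_sched
      applied[i] <- P_i
      bleach_fac <- if (bleaching) exp(-sample$bleach_rate * t_on) else 1
      T_ss <- T_env + P_i * (sample$pce * attn * bleach_fac + q0_frac) / hS
      temps[i + 1L] <- T_ss + (temps[i] - T_ss) * decay
      if (P_i > 0) t_on <- t_on + dt
    }
    applied[n] <- if (controlled) scale * Pvec[n] else Pvec[n]
  }

  if (noise_sd > 0) {
    temps <- run_seeded(seed, function() temps + stats::rnorm(n, 0, noise_sd))
  }

  temperature_trace(times, temps, power = applied,
                    t_off = laser_off_time(laser, duration), T_env = T_env)
}
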