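# Shared fixtures: small systems and traces built in code.

water_system <- function(hS = 0.01, ambient = 25, mass = 0.5) {
  thermal_system(list(thermal_component("water", mass, 4.186)),
                 heat_loss = hS, ambient = ambient)
}

# Constant-temperature trace sampled at `hz` for `minutes`.
constant_trace <- function(temp, minutes, hz = 1) {
  times <- seq(0, minutes * 60, by = 1 / hz)
  temperature_trace(times, rep(temp, length(times)))
}

# Analytic single-exponential cooling trace (plus an on-plateau so t_off
# bookkeeping works): baseline, instantaneous plateau at T_max, cooling tail.
analytic_cooling_trace <- function(tau, T_env = 25, T_max = 55,
                                   heat = 600, cool = 600, dt = 1,
                                   baseline = 30) {
  t_off <- baseline + heat
  times <- seq(0, t_off + cool, by = dt)
  power <- ifelse(times >= baseline & times < t_off, 1, 0)
  temps <- ifelse(
    times < baseline, T_env,
    ifelse(times <= t_off,
           T_env + (T_max - T_env) * (1 - exp(-(times - baseline) / tau)),
           T_env + (T_max - T_env) * exp(-(times - t_off) / tau)))
  # make the plateau exact so T_max_hat is unbiased at short heat times
  temps[times >= baseline & times <= t_off &
          times >= t_off - 0.1 * heat] <- T_max
  temperature_trace(times, temps, power = power, t_off = t_off, T_env = T_env)
}

# Caliper trajectory helper: volumes -> record with a fixed 0.8 aspect.
record_from_volumes <- function(id, group, days, volumes, event = "none",
                                event_day = NA_real_, followup_end = 120) {
  D <- (2 * volumes / 0.8^2)^(1 / 3)
  d <- 0.8 * D
  animal_record(id, group,
                data.frame(day = days, D_mm = D, d_mm = d),
                event = event, event_day = event_day,
                followup_end = followup_end)
}

event_only_record <- function(id, group = "PTT", event = "none",
                              event_day = NA_real_, followup_end = 120) {
  animal_record(id, group,
                data.frame(day = numeric(0), D_mm = numeric(0),
                           d_mm = numeric(0)),
                event = event, event_day = event_day,
                followup_end = followup_end)
}
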