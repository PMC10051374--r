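# Seeded generators of synthetic photothermal experiments and preclinical
# cohorts with known ground truth, used to validate every pipeline stage.

#' Configuration of a synthetic conversion-efficiency experiment
#'
#' Defaults mirror a cuvette experiment on 500 uL of aqueous dispersion at
#' 965 mW: a 30 s pre-laser baseline, 90 min of heating, 10 min of cooling,
#' 1 Hz sampling, and 0.2 degrees C camera noise. The default heat-loss
#' coefficient is chosen so that the relaxation time is 248 s.
#'
#' @param true_eta Ground-truth conversion efficiency in [0, 1].
#' @param components List of [thermal_component()]; default 0.5 g of water.
#' @param hS Heat-loss coefficient in W K^-1; default gives tau_s = 248 s.
#' @param Q0 Nonspecific absorbed power in W at nominal laser power.
#' @param P Laser power in W; default 0.965.
#' @param A_lambda Sample absorbance at the laser wavelength.
#' @param T_env Ambient temperature in degrees C.
#' @param baseline_duration,heat_duration,cool_duration Segment lengths in s.
#' @param dt Sampling interval in s.
#' @param noise_sd Camera noise SD in degrees C.
#' @param bleach_rate Photobleaching rate in s^-1 (0 = photostable).
#' @param seed Mandatory integer seed.
#' @return A list of class `synth_experiment_config`.
#' @export
synth_experiment_config <- function(true_eta = 0.17,
                                    components = list(
                                      thermal_component("water", 0.5, 4.186)),
                                    hS = NULL, Q0 = 0.03, P = 0.965,
                                    A_lambda = 1.0, T_env = 25,
                                    baseline_duration = 30,
                                    heat_duration = 5400,
                                    cool_duration = 600, dt = 1,
                                    noise_sd = 0.2, bleach_rate = 0, seed) {
  if (missing(seed)) ptt_error("`seed` is mandatory for synthetic data")
  sys_probe <- thermal_system(components, ambient = T_env)
  hS <- hS %||% (total_heat_capacity(sys_probe) / 248)
  check_number(true_eta, "true_eta", lower = 0, upper = 1)
  check_number(hS, "hS", lower = 0, strict_lower = TRUE)
  check_number(Q0, "Q0", lower = 0)
  check_number(P, "P", lower = 0, strict_lower = TRUE)
  check_number(A_lambda, "A_lambda", lower = 0, strict_lower = TRUE)
  check_number(baseline_duration, "baseline_duration", lower = 0)
  check_number(heat_duration, "heat_duration", lower = 0, strict_lower = TRUE)
  check_number(cool_duration, "cool_duration", lower = 0)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(bleach_rate, "bleach_rate", lower = 0)
  structure(
    list(true_eta = true_eta, components = components, hS = hS, Q0 = Q0,
         P = P, A_lambda = A_lambda, T_env = T_env,
         baseline_duration = baseline_duration,
         heat_duration = heat_duration, cool_duration = cool_duration,
         dt = dt, noise_sd = noise_sd, bleach_rate = bleach_rate,
         seed = as.integer(seed)),
    class = "synth_experiment_config"
  )
}

#' Generate a synthetic conversion-efficiency experiment
#'
#' Simulates a matched pair of traces: the sample (with the configured
#' ground-truth efficiency) and a blank sharing the same holder, heat loss
#' and nonspecific power but with zero conversion efficiency. The ground
#' truth records every generating parameter, including the implied relaxation
#' time and steady-state temperatures. Deterministic per seed.
#'
#' @param config A [synth_experiment_config()].
#' @return A list: `sample_trace`, `blank_trace`, `truth`.
#' @export
gen_experiment <- function(config) {
  if (!inherits(config, "synth_experiment_config")) {
    ptt_error("`config` must be a synth_experiment_config")
  }
  system <- thermal_system(config$components, heat_loss = config$hS,
                           ambient = config$T_env)
  b <- config$baseline_duration
  duration <- b + config$heat_duration + config$cool_duration
  schedule <- data.frame(start = b, end = b + config$heat_duration,
                         power = config$P)
  laser <- laser_source(config$P, schedule = schedule)
  sample <- optical_sample(config$A_lambda, config$true_eta,
                           baseline_power = config$Q0,
                           bleach_rate = config$bleach_rate)
  blank <- optical_sample(config$A_lambda, 0, baseline_power = config$Q0)

  sample_trace <- simulate_trace(system, sample, laser, duration, config$dt,
                                 noise_sd = config$noise_sd,
                                 seed = config$seed)
  blank_trace <- simulate_trace(system, blank, laser, duration, config$dt,
                                noise_sd = config$noise_sd,
                                seed = config$seed + 1L)
  attn <- 1 - 10^(-config$A_lambda)
  truth <- c(unclass(config)[setdiff(names(config), "components")],
             list(tau_s = relaxation_time(system),
                  heat_capacity = total_heat_capacity(system),
                  T_ss_sample = config$T_env +
                    (config$true_eta * config$P * attn + config$Q0) / config$hS,
                  T_ss_blank = config$T_env + config$Q0 / config$hS))
  list(sample_trace = sample_trace, blank_trace = blank_trace, truth = truth)
}

#' Configuration of a synthetic preclinical PTT cohort
#'
#' Emulates the design of a small-animal photothermal therapy study:
#' nanocarrier administration on day -5, a single 15-min PTT session on day 0
#' capped at 55 degrees C, caliper follow-up every third day through day 120.
#' Group sizes default to the treated-cohort design (4 control, 4 GF females,
#' 5 GFL losartan-pretreated females, 4 GM males; 13 treated animals).
#' Per-animal heterogeneity of nanocarrier uptake enters through a
#' log-normally distributed absorbed power; the probability of complete
#' regression follows a logistic link in log thermal dose,
#' `p = plogis((log(CEM50) - log(dose50)) / dose_slope)`. The dose-response
#' link and its defaults are calibration inventions for testability, not
#' empirical estimates.
#'
#' @param n_per_group Named integer vector of group sizes; the group named
#'   `"control"` is untreated.
#' @param uptake_mean,uptake_cv Mean (W) and coefficient of variation of the
#'   per-animal absorbed laser power.
#' @param controller_threshold Session temperature cap in degrees C.
#' @param step_down Controller power attenuation fraction per action.
#' @param growth_rate Untreated exponential tumor growth rate, day^-1.
#' @param regression_rate Exponential volume decay rate after successful
#'   treatment, day^-1.
#' @param dose50 Dose (minutes CEM50) of 50% regression probability.
#' @param dose_slope Logistic slope parameter on the log-dose scale.
#' @param followup Follow-up horizon in days.
#' @param meas_interval Days between caliper measurements.
#' @param T_env Baseline skin/tumor surface temperature in degrees C.
#' @param tumor_mass,tumor_cp Tumor lump mass (g) and specific heat
#'   (J g^-1 K^-1).
#' @param tumor_hS In vivo heat-loss coefficient in W K^-1.
#' @param P Nominal laser power in W.
#' @param A_lambda Intratumoral absorbance scale used to convert absorbed
#'   power to an effective conversion efficiency.
#' @param session_duration PTT session length in s.
#' @param dt Session sampling interval in s.
#' @param noise_sd Thermal-camera noise SD in degrees C.
#' @param axis_noise_sd Log-scale SD of caliper axis measurement error.
#' @param sacrifice_volume Volume in mm^3 triggering sacrifice.
#' @param seed Mandatory integer seed.
#' @return A list of class `synth_cohort_config`.
#' @export
synth_cohort_config <- function(n_per_group = c(control = 4, GF = 4,
                                                GFL = 5, GM = 4),
                                uptake_mean = 0.34, uptake_cv = 0.25,
                                controller_threshold = 55, step_down = 0.1,
                                growth_rate = 0.25, regression_rate = 0.3,
                                dose50 = 60, dose_slope = 0.5,
                                followup = 120, meas_interval = 3,
                                T_env = 32.5, tumor_mass = 0.12,
                                tumor_cp = 3.5, tumor_hS = 0.015,
                                P = 0.965, A_lambda = 1.0,
                                session_duration = 900, dt = 1,
                                noise_sd = 0.2, axis_noise_sd = 0.03,
                                sacrifice_volume = 2000, seed) {
  if (missing(seed)) ptt_error("`seed` is mandatory for synthetic data")
  n_per_group <- unlist(n_per_group)
  if (is.null(names(n_per_group)) || any(names(n_per_group) == "") ||
      any(n_per_group < 1)) {
    ptt_error("`n_per_group` must be a named vector of positive counts")
  }
  check_number(uptake_mean, "uptake_mean", lower = 0, strict_lower = TRUE)
  check_number(uptake_cv, "uptake_cv", lower = 0)
  check_number(dose50, "dose50", lower = 0, strict_lower = TRUE)
  check_number(dose_slope, "dose_slope", lower = 0, strict_lower = TRUE)
  check_number(growth_rate, "growth_rate", lower = 0, strict_lower = TRUE)
  check_number(regression_rate, "regression_rate", lower = 0,
               strict_lower = TRUE)
  check_number(followup, "followup", lower = 1)
  if (controller_threshold <= T_env) {
    ptt_error("`controller_threshold` must exceed the baseline temperature")
  }
  structure(
    list(n_per_group = n_per_group, uptake_mean = uptake_mean,
         uptake_cv = uptake_cv, controller_threshold = controller_threshold,
         step_down = step_down, growth_rate = growth_rate,
         regression_rate = regression_rate, dose50 = dose50,
         dose_slope = dose_slope, followup = followup,
         meas_interval = meas_interval, T_env = T_env,
         tumor_mass = tumor_mass, tumor_cp = tumor_cp, tumor_hS = tumor_hS,
         P = P, A_lambda = A_lambda, session_duration = session_duration,
         dt = dt, noise_sd = noise_sd, axis_noise_sd = axis_noise_sd,
         sacrifice_volume = sacrifice_volume, seed = as.integer(seed)),
    class = "synth_cohort_config"
  )
}

# Convert a volume to caliper axes assuming a fixed 0.8 short/long aspect.
volume_to_axes <- function(v, aspect = 0.8) {
  D <- (2 * v / aspect^2)^(1 / 3)
  cbind(D = D, d = aspect * D)
}

#' Generate a synthetic preclinical PTT cohort
#'
#' Draws per-animal absorbed powers, simulates each treated animal's
#' temperature-capped PTT session, computes its CEM50 thermal dose, draws the
#' regression outcome from the logistic dose link, and lays down a caliper
#' trajectory: exponential volume decay (to below the caliper detection
#' limit) for regressors, exponential growth at half the untreated rate for
#' non-regressors, and untreated growth for controls. Animals are sacrificed
#' when the measured volume exceeds the sacrifice limit; all others are
#' followed (censored) to the follow-up horizon. Deterministic per seed.
#'
#' @param config A [synth_cohort_config()].
#' @return A list of class `ptt_cohort`: `records` (list of
#'   [animal_record()]), `sessions` (named list of session
#'   [temperature_trace()]s for treated animals), `doses` (data.frame with
#'   animal_id, group, absorbed_W, peak_C, cem50_min, p_regression,
#'   regressed), and `config`.
#' @export
gen_cohort <- function(config) {
  if (!inherits(config, "synth_cohort_config")) {
    ptt_error("`config` must be a synth_cohort_config")
  }
  run_seeded(config$seed, function() gen_cohort_impl(config))
}

gen_cohort_impl <- function(config) {
  tumor_sys <- thermal_system(
    list(thermal_component("tumor", config$tumor_mass, config$tumor_cp)),
    heat_loss = config$tumor_hS, ambient = config$T_env)
  laser <- laser_source(config$P, schedule = data.frame(
    start = 0, end = config$session_duration, power = config$P))
  attn <- 1 - 10^(-config$A_lambda)
  sdlog <- sqrt(log(1 + config$uptake_cv^2))
  meanlog <- log(config$uptake_mean) - sdlog^2 / 2
  days <- seq(0, config$followup, by = config$meas_interval)
  spec50 <- cem50_spec()

  records <- list()
  sessions <- list()
  dose_rows <- list()

  for (g in names(config$n_per_group)) {
    for (i in seq_len(config$n_per_group[[g]])) {
      id <- sprintf("%s-%02d", g, i)
      v0 <- stats::runif(1, 50, 150) # eligible at enrolment by design
      treated <- !identical(g, "control")

      if (treated) {
        absorbed <- stats::rlnorm(1, meanlog, sdlog)
        eta_i <- min(1, absorbed / (config$P * attn))
        samp <- optical_sample(config$A_lambda, eta_i)
        session <- simulate_session(
          tumor_sys, samp, laser, duration = config$session_duration,
          dt = config$dt, threshold = config$controller_threshold,
          step_down = config$step_down, noise_sd = config$noise_sd)
        dose <- cem(session, spec50)
        p_reg <- stats::plogis((log(dose) - log(config$dose50)) /
                                 config$dose_slope)
        regressed <- stats::runif(1) < p_reg
        sessions[[id]] <- session
        dose_rows[[id]] <- data.frame(
          animal_id = id, group = g, absorbed_W = absorbed,
          peak_C = max(session$temps), cem50_min = dose,
          p_regression = p_reg, regressed = regressed)
      } else {
        regressed <- FALSE
      }

      rate <- if (!treated) {
        config$growth_rate
      } else if (regressed) {
        -config$regression_rate
      } else {
        config$growth_rate / 2
      }
      v <- v0 * exp(rate * days)
      v[v < 0.5] <- 0 # below caliper detection limit

      # caliper noise on the axes; volumes of 0 stay 0
      ax <- volume_to_axes(v)
      if (config$axis_noise_sd > 0) {
        ax <- ax * exp(matrix(stats::rnorm(length(ax), 0,
                                           config$axis_noise_sd),
                              ncol = 2))
        swap <- ax[, 2L] > ax[, 1L]
        if (any(swap)) ax[swap, ] <- ax[swap, 2:1]
      }
      ax[v == 0, ] <- 0

      v_meas <- ax[, 1L] * ax[, 2L]^2 / 2
      over <- which(v_meas > config$sacrifice_volume)
      if (length(over) > 0L) {
        cut <- over[1L]
        meas <- data.frame(day = days[seq_len(cut)],
                           D_mm = ax[seq_len(cut), 1L],
                           d_mm = ax[seq_len(cut), 2L])
        rec <- animal_record(id, g, meas, event = "sacrifice",
                             event_day = days[cut],
                             followup_end = config$followup)
      } else {
        meas <- data.frame(day = days, D_mm = ax[, 1L], d_mm = ax[, 2L])
        rec <- animal_record(id, g, meas, event = "none",
                             followup_end = config$followup)
      }
      records[[id]] <- rec
    }
  }

  doses <- if (length(dose_rows)) {
    do.call(rbind, c(dose_rows, list(make.row.names = FALSE)))
  } else {
    data.frame()
  }
  structure(list(records = records, sessions = sessions, doses = doses,
                 config = config),
            class = "ptt_cohort")
}

#' @export
print.ptt_cohort <- function(x, ...) {
  cat(sprintf("<ptt_cohort> %d animals (%d treated sessions), seed %d\n",
              length(x$records), length(x$sessions), x$config$seed))
  invisible(x)
}
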