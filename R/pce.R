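# Cooling-regime estimation of tau_s, hS, Q0 and the photothermal
# conversion efficiency from time-temperature traces (energy-balance method).

# Resolve the ambient temperature for a trace: explicit override, then the
# mean of leading zero-power (pre-laser) samples, then the trace's own
# recorded ambient.
resolve_T_env <- function(trace, T_env = NULL) {
  if (!is.null(T_env)) return(T_env)
  if (!is.null(trace$power)) {
    first_on <- which(trace$power > 0)[1L]
    if (!is.na(first_on) && first_on > 1L) {
      return(mean(trace$temps[seq_len(first_on - 1L)]))
    }
  }
  if (!is.null(trace$T_env)) return(trace$T_env)
  ptt_error(paste("ambient temperature unknown: supply `T_env`, include a",
                  "pre-laser baseline, or record it in the trace"))
}

# Indices of laser-on samples (positive power when recorded, otherwise all
# samples up to t_off).
laser_on_idx <- function(trace) {
  if (is.null(trace$t_off)) {
    ptt_error("trace has no laser-off instant (`t_off`): no cooling regime")
  }
  on <- trace$times <= trace$t_off
  if (!is.null(trace$power)) on <- on & trace$power > 0
  which(on)
}

#' Fit the cooling curve of a trace
#'
#' Estimates the thermal relaxation time tau_s by least squares on the
#' laser-off tail of a trace, using the single-exponential cooling law
#' `T(t) = T_env + (T_max - T_env) * exp(-(t - t_off) / tau_s)`. The ambient
#' temperature is pinned from the pre-laser baseline (or an override) and the
#' steady-state temperature from the tail of the laser-on record, leaving
#' tau_s as the only free parameter; this avoids the noise bias of
#' log-linearizing the decay.
#'
#' @param trace A [temperature_trace()] with `t_off` set.
#' @param settle Seconds discarded immediately after laser-off (camera and
#'   convection transients). Default 5 s.
#' @param tail_frac Fraction of the laser-on samples (from the end) averaged
#'   to estimate the steady-state temperature T_max. Default 0.1.
#' @param T_env Optional ambient-temperature override in degrees C.
#' @param min_delta Minimum credible steady-state rise (T_max - T_env) in
#'   degrees C; smaller rises are rejected as insufficient signal.
#' @return An object of class `cooling_fit` with fields `tau_s`, `hS`
#'   (`NA` until combined with a heat capacity, see [infer_hS()]),
#'   `T_env_hat`, `T_max_hat`, `rmse`, `n_points`, and `window`.
#' @export
fit_cooling <- function(trace, settle = 5, tail_frac = 0.1, T_env = NULL,
                        min_delta = 0.5) {
  if (!inherits(trace, "temperature_trace")) {
    ptt_error("`trace` must be a temperature_trace")
  }
  if (is.null(trace$t_off)) {
    ptt_error("trace has no laser-off instant (`t_off`): no cooling regime")
  }
  check_number(settle, "settle", lower = 0)
  check_number(tail_frac, "tail_frac", lower = 0, upper = 1,
               strict_lower = TRUE)

  T_env_hat <- resolve_T_env(trace, T_env)
  on_idx <- laser_on_idx(trace)
  if (length(on_idx) < 1L) {
    ptt_error("no laser-on samples before t_off",
              class = "pttdose_insufficient_data")
  }
  n_tail <- max(1L, ceiling(tail_frac * length(on_idx)))
  T_max_hat <- mean(trace$temps[utils::tail(on_idx, n_tail)])

  cool <- which(trace$times >= trace$t_off + settle &
                  trace$times <= trace$t_final)
  if (length(cool) < 5L) {
    ptt_error("fewer than 5 usable cooling samples after t_off + settle",
              class = "pttdose_insufficient_data")
  }
  if ((T_max_hat - T_env_hat) < min_delta) {
    ptt_error(sprintf(
      "steady-state rise %.3g C is below min_delta = %g C: no cooling signal",
      T_max_hat - T_env_hat, min_delta), class = "pttdose_insufficient_signal")
  }

  tc <- trace$times[cool] - trace$t_off
  y <- trace$temps[cool]
  amp <- T_max_hat - T_env_hat
  ssq <- function(tau) sum((T_env_hat + amp * exp(-tc / tau) - y)^2)
  upper <- 200 * max(tc)
  opt <- stats::optimize(ssq, interval = c(max(tc) * 1e-4, upper),
                         tol = 1e-7)
  tau_s <- opt$minimum
  rmse <- sqrt(opt$objective / length(tc))

  structure(
    list(tau_s = tau_s, hS = NA_real_, T_env_hat = T_env_hat,
         T_max_hat = T_max_hat, rmse = rmse, n_points = length(tc),
         window = c(start = trace$times[cool[1L]],
                    end = trace$times[cool[length(cool)]])),
    class = "cooling_fit"
  )
}

#' @export
print.cooling_fit <- function(x, ...) {
  cat(sprintf(
    "<cooling_fit> tau_s = %.4g s (n = %d, rmse = %.3g C)\n  T_env = %.3f C, T_max = %.3f C\n",
    x$tau_s, x$n_points, x$rmse, x$T_env_hat, x$T_max_hat))
  invisible(x)
}

#' Heat-loss coefficient from a relaxation time
#'
#' Inverts the relaxation-time relation: hS equals the total heat capacity of
#' the system divided by tau_s.
#'
#' @param tau_s Relaxation time in seconds (> 0), or a `cooling_fit`.
#' @param system A [thermal_system()] supplying the heat capacity.
#' @return hS in W K^-1.
#' @export
infer_hS <- function(tau_s, system) {
  if (inherits(tau_s, "cooling_fit")) tau_s <- tau_s$tau_s
  check_number(tau_s, "tau_s", lower = 0, strict_lower = TRUE)
  total_heat_capacity(system) / tau_s
}

#' Nonspecific absorbed power from a blank record
#'
#' Estimates Q0, the power absorbed by the sample holder and carrier liquid
#' alone, from the steady state of a blank (nanomaterial-free) trace:
#' Q0 = hS_blank * (T_max_blank - T_env), with hS_blank obtained from the
#' blank's own cooling fit. The blank must have reached steady state: the
#' slope over the final `plateau_window` seconds of laser-on data must be
#' below `slope_tol`. A blank that never heats measurably above ambient
#' yields Q0 = 0.
#'
#' @param blank_trace A [temperature_trace()] of the blank, with `t_off`.
#' @param blank_system A [thermal_system()] describing the blank.
#' @param settle,tail_frac,T_env Passed to [fit_cooling()].
#' @param slope_tol Maximum admissible plateau slope in degrees C per second.
#'   Default 0.005.
#' @param plateau_window Length of the plateau-check window in seconds.
#'   Default 60.
#' @param zero_delta Rise below which the blank is treated as unheated and
#'   Q0 = 0 is returned. Default 0.25 degrees C.
#' @return Q0 in W.
#' @export
estimate_q0 <- function(blank_trace, blank_system, settle = 5,
                        tail_frac = 0.1, T_env = NULL, slope_tol = 0.005,
                        plateau_window = 60, zero_delta = 0.25) {
  if (!inherits(blank_trace, "temperature_trace")) {
    ptt_error("`blank_trace` must be a temperature_trace")
  }
  if (is.null(blank_trace$t_off)) {
    ptt_error("blank trace has no laser-off instant (`t_off`)")
  }
  check_plateau(blank_trace, slope_tol, plateau_window, what = "blank")

  T_env_hat <- resolve_T_env(blank_trace, T_env)
  on_idx <- laser_on_idx(blank_trace)
  n_tail <- max(1L, ceiling(tail_frac * length(on_idx)))
  T_max_hat <- mean(blank_trace$temps[utils::tail(on_idx, n_tail)])
  if ((T_max_hat - T_env_hat) < zero_delta) {
    return(0)
  }
  fit <- fit_cooling(blank_trace, settle = settle, tail_frac = tail_frac,
                     T_env = T_env, min_delta = zero_delta)
  hS_blank <- infer_hS(fit$tau_s, blank_system)
  hS_blank * (fit$T_max_hat - fit$T_env_hat)
}

# Steady-state check: linear slope of the last `window` seconds of laser-on
# samples must be below `slope_tol` in absolute value.
check_plateau <- function(trace, slope_tol, window, what = "trace") {
  on_idx <- laser_on_idx(trace)
  if (length(on_idx) < 5L) {
    ptt_error(sprintf("%s has too few laser-on samples", what),
              class = "pttdose_insufficient_data")
  }
  t_on <- trace$times[on_idx]
  sel <- on_idx[t_on >= max(t_on) - window]
  if (length(sel) < 3L) sel <- utils::tail(on_idx, 3L)
  slope <- stats::coef(stats::lm(trace$temps[sel] ~ trace$times[sel]))[2L]
  if (abs(slope) > slope_tol) {
    ptt_error(sprintf(
      "%s has not reached steady state: plateau slope %.4g C/s exceeds %g C/s",
      what, slope, slope_tol), class = "pttdose_nonstationary")
  }
  invisible(slope)
}

#' Dilution correction of a measured absorbance
#'
#' Scales an absorbance measured on a diluted aliquot back to the working
#' concentration assuming Beer-Lambert linearity. Warns when the measured
#' absorbance exceeds 1, where instrument linearity is commonly degraded.
#'
#' @param measured_A Measured absorbance, >= 0.
#' @param dilution_factor Dilution factor, >= 1.
#' @return Corrected absorbance.
#' @export
correct_absorbance <- function(measured_A, dilution_factor = 1) {
  check_number(measured_A, "measured_A", lower = 0)
  check_number(dilution_factor, "dilution_factor", lower = 1)
  if (measured_A > 1) {
    warning("measured absorbance > 1: outside the usual linear range of ",
            "Beer-Lambert photometry", call. = FALSE)
  }
  measured_A * dilution_factor
}

#' Photothermal conversion efficiency from steady-state quantities
#'
#' Energy-balance estimate of the conversion efficiency:
#' `eta = (hS * (T_max - T_env) - Q0) / (P * (1 - 10^-A))`. At steady state
#' the heat dissipated, hS * (T_max - T_env), equals the total absorbed
#' power; subtracting the nonspecific part Q0 and dividing by the power
#' absorbed by the sample gives the fraction converted to heat. Estimates
#' outside [0, 1] are returned flagged (`in_range = FALSE`) with a warning,
#' never silently clipped.
#'
#' @param T_max Steady-state temperature in degrees C.
#' @param T_env Ambient temperature in degrees C; `T_max > T_env` required.
#' @param Q0 Nonspecific absorbed power in W.
#' @param P Laser power in W, > 0.
#' @param A_lambda Absorbance at the laser wavelength, > 0.
#' @param hS Heat-loss coefficient in W K^-1, > 0.
#' @return An object of class `pce_result`: fields `eta`, `in_range`, and
#'   `components` (dissipated power, Q0, P, attenuation factor).
#' @examples
#' compute_pce(T_max = 55, T_env = 25, Q0 = 0.03, P = 1, A_lambda = 1,
#'             hS = 0.01) # eta = 0.30
#' @export
compute_pce <- function(T_max, T_env, Q0, P, A_lambda, hS) {
  check_number(T_max, "T_max")
  check_number(T_env, "T_env")
  check_number(Q0, "Q0", lower = 0)
  check_number(P, "P", lower = 0, strict_lower = TRUE)
  check_number(A_lambda, "A_lambda", lower = 0)
  check_number(hS, "hS", lower = 0, strict_lower = TRUE)
  if (T_max <= T_env) ptt_error("`T_max` must exceed `T_env`")
  if (A_lambda == 0) {
    ptt_error("A_lambda = 0: the sample absorbs no light, eta is undefined",
              class = "pttdose_degenerate_input")
  }
  attn <- 1 - 10^(-A_lambda)
  dissipated <- hS * (T_max - T_env)
  eta <- (dissipated - Q0) / (P * attn)
  in_range <- eta >= 0 && eta <= 1
  if (!in_range) {
    warning(sprintf("estimated eta = %.4g lies outside [0, 1]; result flagged",
                    eta), call. = FALSE)
  }
  structure(
    list(eta = eta, in_range = in_range,
         components = list(dissipated_W = dissipated, Q0_W = Q0, P_W = P,
                           attenuation = attn)),
    class = "pce_result"
  )
}

#' @export
print.pce_result <- function(x, ...) {
  cat(sprintf("<pce_result> eta = %.4f (%s)\n", x$eta,
              if (x$in_range) "in range" else "FLAGGED: outside [0, 1]"))
  cat(sprintf("  dissipated = %.4g W, Q0 = %.4g W, P = %.4g W, 1-10^-A = %.4g\n",
              x$components$dissipated_W, x$components$Q0_W,
              x$components$P_W, x$components$attenuation))
  if (!is.null(x$tau_s)) {
    cat(sprintf("  tau_s = %.4g s, hS = %.4g W/K\n", x$tau_s, x$hS))
  }
  invisible(x)
}

#' Full conversion-efficiency experiment analysis
#'
#' Chains the whole cooling-regime workflow on a sample trace and a blank
#' trace: cooling fit of the sample (tau_s), heat-loss coefficient from the
#' system heat capacity, nonspecific power from the blank, and the
#' energy-balance efficiency. The heat-loss geometry is assumed identical for
#' sample and blank (same holder). The sample trace must have reached steady
#' state before laser-off; a declining (photobleaching) plateau is rejected.
#'
#' @param sample_trace,blank_trace [temperature_trace()] objects with `t_off`.
#' @param system [thermal_system()] of the sample.
#' @param blank_system [thermal_system()] of the blank; defaults to `system`.
#' @param P Laser power in W.
#' @param A_lambda Sample absorbance at the laser wavelength.
#' @param settle,tail_frac,T_env Passed to the underlying fits.
#' @param slope_tol,plateau_window Steady-state check, see [estimate_q0()].
#' @return A `pce_result` augmented with `tau_s`, `hS`, `Q0` and the sample
#'   `cooling_fit`.
#' @export
estimate_pce_experiment <- function(sample_trace, blank_trace, system,
                                    blank_system = system, P, A_lambda,
                                    settle = 5, tail_frac = 0.1,
                                    T_env = NULL, slope_tol = 0.005,
                                    plateau_window = 60) {
  stage <- function(name, expr) {
    tryCatch(expr, pttdose_error = function(e) {
      ptt_error(sprintf("[%s] %s", name, conditionMessage(e)),
                class = class(e)[1L])
    })
  }
  stage("sample steady-state check",
        check_plateau(sample_trace, slope_tol, plateau_window,
                      what = "sample trace"))
  fit <- stage("fit_cooling(sample)",
               fit_cooling(sample_trace, settle = settle,
                           tail_frac = tail_frac, T_env = T_env))
  hS <- stage("infer_hS", infer_hS(fit$tau_s, system))
  Q0 <- stage("estimate_q0(blank)",
              estimate_q0(blank_trace, blank_system, settle = settle,
                          tail_frac = tail_frac, T_env = T_env,
                          slope_tol = slope_tol,
                          plateau_window = plateau_window))
  res <- stage("compute_pce",
               compute_pce(fit$T_max_hat, fit$T_env_hat, Q0, P, A_lambda, hS))
  res$tau_s <- fit$tau_s
  res$hS <- hS
  res$Q0 <- Q0
  res$fit <- fit
  res
}
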