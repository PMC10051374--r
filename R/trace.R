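#' Sampled time-temperature trace
#'
#' A thermal-camera style time series: sampling times (s), temperatures
#' (degrees C), an optional per-sample applied laser power (W), the laser-off
#' instant `t_off` (s) when the record contains a cooling tail, and the
#' analysis window `[t0, t_final]` (defaults to the full record). An optional
#' ambient temperature can be attached; readers and simulators set it when
#' known so downstream fits need not re-estimate it.
#'
#' @param times Sampling times in seconds, strictly increasing.
#' @param temps Temperatures in degrees C, same length as `times`.
#' @param power Optional applied laser power in W at each sample.
#' @param t_off Optional laser-off instant in seconds.
#' @param t0,t_final Analysis window bounds in seconds; default full record.
#' @param T_env Optional known ambient temperature in degrees C.
#' @return An object of class `temperature_trace`.
#' @export
temperature_trace <- function(times, temps, power = NULL, t_off = NULL,
                              t0 = NULL, t_final = NULL, T_env = NULL) {
  if (!is.numeric(times) || !is.numeric(temps)) {
    ptt_error("`times` and `temps` must be numeric")
  }
  n <- length(times)
  if (n < 2L) ptt_error("a trace needs at least two samples")
  if (length(temps) != n) ptt_error("`times` and `temps` lengths differ")
  if (any(diff(times) <= 0)) {
    ptt_error("`times` must be strictly increasing")
  }
  if (!is.null(power)) {
    if (!is.numeric(power) || length(power) != n) {
      ptt_error("`power` must be numeric with one value per sample")
    }
    if (any(power < 0)) ptt_error("`power` must be >= 0")
  }
  t0 <- t0 %||% times[1L]
  t_final <- t_final %||% times[n]
  if (t0 < times[1L] || t_final > times[n] || t0 >= t_final) {
    ptt_error("analysis window [t0, t_final] must lie within the sampled range")
  }
  if (!is.null(t_off)) check_number(t_off, "t_off")
  if (!is.null(T_env)) check_number(T_env, "T_env")
  structure(
    list(times = times, temps = temps, power = power, t_off = t_off,
         t0 = t0, t_final = t_final, T_env = T_env),
    class = "temperature_trace"
  )
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf(
    "<temperature_trace> %d samples, t = [%g, %g] s, T = [%.2f, %.2f] C\n",
    length(x$times), x$times[1L], x$times[length(x$times)],
    min(x$temps), max(x$temps)))
  if (!is.null(x$t_off)) cat(sprintf("  laser off at t = %g s\n", x$t_off))
  if (!is.null(x$power)) {
    cat(sprintf("  power recorded, max %.3f W\n", max(x$power)))
  }
  invisible(x)
}

#' Dimensionless temperature of a trace
#'
#' Rescales a temperature record to the dimensionless driving temperature
#' Theta(t) = (T_env - T(t)) / (T_env - T_max), so that Theta = 1 at the
#' maximum (steady-state) temperature and Theta = 0 at ambient. During
#' free cooling of a lumped system Theta(t) = exp(-t / tau_s).
#'
#' @param trace A [temperature_trace()].
#' @param T_env Ambient temperature in degrees C.
#' @param T_max Maximum (steady-state) temperature in degrees C; must differ
#'   from `T_env`.
#' @return An object of class `dimensionless_trace` with fields `times` and
#'   `theta`.
#' @export
dimensionless_theta <- function(trace, T_env, T_max) {
  if (!inherits(trace, "temperature_trace")) {
    ptt_error("`trace` must be a temperature_trace")
  }
  check_number(T_env, "T_env")
  check_number(T_max, "T_max")
  if (T_max == T_env) {
    ptt_error("T_max equals T_env: dimensionless temperature is undefined",
              class = "pttdose_degenerate_input")
  }
  structure(
    list(times = trace$times,
         theta = (T_env - trace$temps) / (T_env - T_max)),
    class = "dimensionless_trace"
  )
}
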