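#' Thermal component of a lumped sample
#'
#' One material making up the irradiated system (sample holder, carrier
#' liquid, nanocarrier dispersion, tumor tissue ...), described by its mass
#' and specific heat. The product mass x specific heat is the component's
#' contribution to the total heat capacity of the lumped system.
#'
#' @param name Label for the material.
#' @param mass Mass in grams, strictly positive.
#' @param specific_heat Specific heat in J g^-1 K^-1, strictly positive.
#' @return An object of class `thermal_component`.
#' @examples
#' thermal_component("water", mass = 0.5, specific_heat = 4.186)
#' @export
thermal_component <- function(name, mass, specific_heat) {
  if (!is.character(name) || length(name) != 1L) {
    ptt_error("`name` must be a single string")
  }
  check_number(mass, "mass", lower = 0, strict_lower = TRUE)
  check_number(specific_heat, "specific_heat", lower = 0, strict_lower = TRUE)
  structure(
    list(name = name, mass = mass, specific_heat = specific_heat),
    class = "thermal_component"
  )
}

#' Lumped thermal system
#'
#' The lumped-capacitance description of an irradiated sample: its material
#' components, the heat-loss coefficient hS (heat transfer coefficient times
#' irradiated surface area, in W K^-1) and the ambient temperature. hS may be
#' left unset (`NA`) before it has been determined from a cooling fit.
#'
#' @param components A list of [thermal_component()] objects (non-empty).
#' @param heat_loss hS in W K^-1, strictly positive when set; `NA` if unknown.
#' @param ambient Ambient (environment) temperature T_env in degrees C.
#' @return An object of class `thermal_system`.
#' @seealso [total_heat_capacity()], [relaxation_time()]
#' @examples
#' sys <- thermal_system(
#'   list(thermal_component("water", 0.5, 4.186)),
#'   heat_loss = 8.83e-3, ambient = 25
#' )
#' relaxation_time(sys)
#' @export
thermal_system <- function(components, heat_loss = NA_real_, ambient = 25) {
  if (inherits(components, "thermal_component")) components <- list(components)
  if (!is.list(components) || length(components) == 0L) {
    ptt_error("`components` must be a non-empty list of thermal components")
  }
  ok <- vapply(components, inherits, logical(1), "thermal_component")
  if (!all(ok)) ptt_error("all `components` must be thermal_component objects")
  check_number(heat_loss, "heat_loss", lower = 0, strict_lower = TRUE,
               allow_na = TRUE)
  check_number(ambient, "ambient")
  structure(
    list(components = components, heat_loss = heat_loss, ambient = ambient),
    class = "thermal_system"
  )
}

#' Total heat capacity of a lumped system
#'
#' Sum over components of mass times specific heat.
#'
#' @param system A [thermal_system()].
#' @return Total heat capacity in J K^-1.
#' @examples
#' sys <- thermal_system(list(thermal_component("water", 0.5, 4.186)))
#' total_heat_capacity(sys) # 2.093
#' @export
total_heat_capacity <- function(system) {
  if (!inherits(system, "thermal_system")) {
    ptt_error("`system` must be a thermal_system")
  }
  sum(vapply(system$components,
             function(co) co$mass * co$specific_heat, numeric(1)))
}

#' Thermal relaxation time
#'
#' The exponential time constant governing heating and cooling of the lumped
#' system: total heat capacity divided by the heat-loss coefficient hS.
#'
#' @param system A [thermal_system()] with `heat_loss` set.
#' @return Relaxation time tau_s in seconds.
#' @examples
#' sys <- thermal_system(list(thermal_component("water", 0.5, 4.186)),
#'                       heat_loss = 8.83e-3)
#' relaxation_time(sys) # ~237 s
#' @export
relaxation_time <- function(system) {
  if (!inherits(system, "thermal_system")) {
    ptt_error("`system` must be a thermal_system")
  }
  hS <- system$heat_loss
  if (is.na(hS) || hS <= 0) {
    ptt_error("`heat_loss` (hS) must be set and > 0 to compute tau_s")
  }
  total_heat_capacity(system) / hS
}

#' Optical description of a photothermal sample
#'
#' Absorbance at the laser wavelength, photothermal conversion efficiency
#' (the fraction of the absorbed laser power converted into heat), the
#' nonspecific power absorbed by the sample holder and carrier liquid, and an
#' optional first-order photobleaching rate for dyes whose absorption decays
#' under irradiation (0 = photostable).
#'
#' @param absorbance A_lambda, dimensionless, >= 0.
#' @param pce Conversion efficiency eta, a fraction in [0, 1].
#' @param baseline_power Nonspecific absorbed power Q0 in W, >= 0, referred
#'   to the nominal laser power.
#' @param bleach_rate First-order decay rate of the specific absorbed power
#'   with accumulated laser-on time, in s^-1, >= 0.
#' @return An object of class `optical_sample`.
#' @export
optical_sample <- function(absorbance, pce, baseline_power = 0,
                           bleach_rate = 0) {
  check_number(absorbance, "absorbance", lower = 0)
  check_number(pce, "pce", lower = 0, upper = 1)
  check_number(baseline_power, "baseline_power", lower = 0)
  check_number(bleach_rate, "bleach_rate", lower = 0)
  structure(
    list(absorbance = absorbance, pce = pce,
         baseline_power = baseline_power, bleach_rate = bleach_rate),
    class = "optical_sample"
  )
}

#' Laser source with a power schedule
#'
#' A continuous-wave laser described by its nominal power, wavelength, and an
#' ordered, non-overlapping schedule of constant-power segments. Times
#' outside every segment carry zero power (laser off).
#'
#' @param power Nominal power P in W, >= 0.
#' @param wavelength Wavelength in nm.
#' @param schedule A data.frame with columns `start`, `end` (s, strictly
#'   increasing, non-overlapping) and `power` (W, >= 0). Default: a single
#'   segment at nominal power from 0 to Inf.
#' @return An object of class `laser_source`.
#' @export
laser_source <- function(power, wavelength = 808, schedule = NULL) {
  check_number(power, "power", lower = 0)
  check_number(wavelength, "wavelength", lower = 0, strict_lower = TRUE)
  if (is.null(schedule)) {
    schedule <- data.frame(start = 0, end = Inf, power = power)
  }
  if (!is.data.frame(schedule) ||
      !all(c("start", "end", "power") %in% names(schedule))) {
    ptt_error("`schedule` must have columns start, end, power")
  }
  schedule <- schedule[order(schedule$start), , drop = FALSE]
  if (any(schedule$end <= schedule$start)) {
    ptt_error("schedule segment times must be strictly increasing")
  }
  if (nrow(schedule) > 1L &&
      any(schedule$start[-1L] < schedule$end[-nrow(schedule)])) {
    ptt_error("schedule segments must not overlap")
  }
  if (any(schedule$power < 0)) ptt_error("schedule powers must be >= 0")
  structure(
    list(power = power, wavelength = wavelength, schedule = schedule),
    class = "laser_source"
  )
}

# Scheduled power at each time point (left-continuous lookup: the power of
# the segment whose [start, end) interval contains t; 0 between segments).
power_at <- function(laser, times) {
  out <- numeric(length(times))
  for (k in seq_len(nrow(laser$schedule))) {
    seg <- laser$schedule[k, ]
    sel <- times >= seg$start & times < seg$end
    out[sel] <- seg$power
  }
  out
}

# Laser-off instant within [0, duration]: end of the last positive-power
# segment, or NULL if the laser is still on at the end of the record.
laser_off_time <- function(laser, duration) {
  pos <- laser$schedule[laser$schedule$power > 0, , drop = FALSE]
  if (nrow(pos) == 0L) return(NULL)
  t_end <- min(max(pos$end), duration)
  if (t_end < duration) t_end else NULL
}
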