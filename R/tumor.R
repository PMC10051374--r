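#' Ellipsoidal tumor volume from caliper axes
#'
#' Standard preclinical caliper volumetry assuming an ellipsoidal tumor:
#' `V = D * d^2 / 2`, with D the long axis and d the short axis in mm.
#' Vectorized over measurements.
#'
#' @param D Long axis in mm, >= 0.
#' @param d Short axis in mm, 0 <= d <= D.
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(10, 10) # 500
#' tumor_volume(12, 8)  # 384
#' @export
tumor_volume <- function(D, d) {
  if (!is.numeric(D) || !is.numeric(d) || length(D) != length(d)) {
    ptt_error("`D` and `d` must be numeric vectors of equal length")
  }
  if (any(is.na(D)) || any(is.na(d))) ptt_error("axes must not contain NA")
  if (any(D < 0) || any(d < 0)) ptt_error("axes must be >= 0")
  if (any(d > D)) ptt_error("short axis `d` must not exceed long axis `D`")
  D * d^2 / 2
}

#' Eligibility of a tumor volume for treatment
#'
#' Inclusive-bounds volume window for enrolment (default 50-150 mm^3).
#'
#' @param volume Tumor volume(s) in mm^3.
#' @param low,high Window bounds in mm^3, `low < high`. Both inclusive.
#' @return Logical vector.
#' @export
is_eligible <- function(volume, low = 50, high = 150) {
  check_number(low, "low")
  check_number(high, "high")
  if (low >= high) ptt_error("`low` must be less than `high`")
  volume >= low & volume <= high
}

#' Animal record: caliper trajectory and outcome
#'
#' One animal's identity, experimental group, caliper trajectory (day
#' relative to the treatment day 0; nanocarrier administration is day -5),
#' and its survival outcome: `"none"` (alive through follow-up, censored),
#' `"death"`, or `"sacrifice"` with the event day.
#'
#' @param animal_id Label.
#' @param group Group label (e.g. control, GF, GFL, GM).
#' @param measurements A data.frame with columns `day`, `D_mm`, `d_mm`
#'   (may have zero rows when an event precluded measurement).
#' @param event One of `"none"`, `"death"`, `"sacrifice"`.
#' @param event_day Day of the event; required when `event != "none"` and at
#'   most `followup_end`.
#' @param followup_end Last follow-up day; default 120.
#' @return An object of class `animal_record`.
#' @export
animal_record <- function(animal_id, group, measurements,
                          event = c("none", "death", "sacrifice"),
                          event_day = NA_real_, followup_end = 120) {
  event <- match.arg(event)
  if (!is.data.frame(measurements) ||
      !all(c("day", "D_mm", "d_mm") %in% names(measurements))) {
    ptt_error("`measurements` must have columns day, D_mm, d_mm")
  }
  measurements <- measurements[order(measurements$day), , drop = FALSE]
  if (nrow(measurements) > 0L) {
    tumor_volume(measurements$D_mm, measurements$d_mm) # validates axes
  }
  check_number(followup_end, "followup_end", lower = 0)
  if (event != "none") {
    check_number(event_day, "event_day")
    if (event_day > followup_end) {
      ptt_error("`event_day` must not exceed `followup_end`")
    }
  }
  structure(
    list(animal_id = animal_id, group = group, measurements = measurements,
         event = event, event_day = if (event == "none") NA_real_ else event_day,
         followup_end = followup_end),
    class = "animal_record"
  )
}

#' Classify the post-treatment outcome of an animal
#'
#' Reproducible outcome labels from a caliper trajectory. Using volumes on
#' post-treatment days (day >= 0):
#' * `complete_regression` - the trajectory ends in a run of at least
#'   `confirm_n` consecutive measurements below `regression_threshold`
#'   sustained through the last measurement;
#' * `recurrence` - a confirmed regression run is later followed by at least
#'   2 consecutive measurements back above the threshold;
#' * `progression` - the volume never falls below the threshold and the final
#'   volume exceeds the initial one;
#' * `non_evaluable` - anything else, e.g. an early death leaving fewer than
#'   two post-treatment measurements.
#'
#' Labels depend only on the ordered volume sequence, so they are invariant
#' to rescaling of the measurement days.
#'
#' @param record An [animal_record()].
#' @param regression_threshold Volume in mm^3 below which a tumor counts as
#'   regressed. Default 5.
#' @param confirm_n Consecutive sub-threshold measurements required to
#'   confirm regression. Default 2.
#' @return An object of class `outcome_label`: `label` plus the `basis`
#'   thresholds used.
#' @export
classify_outcome <- function(record, regression_threshold = 5, confirm_n = 2) {
  if (!inherits(record, "animal_record")) {
    ptt_error("`record` must be an animal_record")
  }
  check_number(regression_threshold, "regression_threshold", lower = 0)
  check_number(confirm_n, "confirm_n", lower = 1)
  meas <- record$measurements[record$measurements$day >= 0, , drop = FALSE]
  if (nrow(meas) == 0L && record$event == "none") {
    ptt_error("record has no post-treatment measurements and no event")
  }
  basis <- list(regression_threshold = regression_threshold,
                confirm_n = confirm_n)
  lab <- function(label) structure(list(label = label, basis = basis),
                                   class = "outcome_label")
  if (nrow(meas) < 2L) return(lab("non_evaluable"))

  v <- tumor_volume(meas$D_mm, meas$d_mm)
  below <- v < regression_threshold
  runs <- rle(below)
  k <- length(runs$lengths)
  confirmed <- which(runs$values & runs$lengths >= confirm_n)

  if (length(confirmed) > 0L && runs$values[k] &&
      runs$lengths[k] >= confirm_n) {
    return(lab("complete_regression"))
  }
  if (length(confirmed) > 0L) {
    after <- seq_len(k) > min(confirmed)
    if (any(after & !runs$values & runs$lengths >= 2L)) {
      return(lab("recurrence"))
    }
  }
  if (!any(below) && v[length(v)] > v[1L]) return(lab("progression"))
  lab("non_evaluable")
}

#' @export
print.outcome_label <- function(x, ...) {
  cat(sprintf("<outcome_label> %s (threshold %g mm^3, confirm %d)\n",
              x$label, x$basis$regression_threshold, x$basis$confirm_n))
  invisible(x)
}

#' Kaplan-Meier survival of a cohort
#'
#' Product-limit survival estimate over a cohort of animal records. Deaths
#' and sacrifices are events at their event day; animals alive through
#' follow-up are censored at the horizon (or at their follow-up end when that
#' is earlier).
#'
#' @param records A non-empty list of [animal_record()] objects.
#' @param horizon Day at which the survival fraction is reported; default 120.
#' @return A list of class `km_result`: `curve` (data.frame time, n_risk,
#'   n_event, surv), `surv_at_horizon` (fraction), `surv_pct` (percentage
#'   rounded to the nearest integer), `n`, `n_events`, and the underlying
#'   `survival::survfit` object as `fit`.
#' @examples
#' rec <- function(id, event, day) {
#'   animal_record(id, "PTT", data.frame(day = numeric(0), D_mm = numeric(0),
#'                                       d_mm = numeric(0)),
#'                 event = event, event_day = day)
#' }
#' cohort <- c(list(rec("a", "death", 10), rec("b", "sacrifice", 45)),
#'             lapply(3:13, function(i) rec(paste0("s", i), "none", NA)))
#' km_survival(cohort, horizon = 120)$surv_pct # 85
#' @export
km_survival <- function(records, horizon = 120) {
  if (!is.list(records) || length(records) == 0L ||
      !all(vapply(records, inherits, logical(1), "animal_record"))) {
    ptt_error("`records` must be a non-empty list of animal_record objects")
  }
  check_number(horizon, "horizon", lower = 0)
  obs <- vapply(records, function(r) {
    if (r$event != "none") r$event_day else r$followup_end
  }, numeric(1))
  if (horizon < min(obs)) {
    ptt_error("`horizon` precedes every observation time")
  }
  time <- vapply(records, function(r) {
    if (r$event != "none") r$event_day else min(r$followup_end, horizon)
  }, numeric(1))
  status <- vapply(records, function(r) as.integer(r$event != "none"),
                   integer(1))
  fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  s_h <- summary(fit, times = horizon, extend = TRUE)$surv
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv)
  structure(
    list(curve = curve, surv_at_horizon = s_h,
         surv_pct = round(100 * s_h), n = length(records),
         n_events = sum(status), fit = fit),
    class = "km_result"
  )
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result> n = %d, events = %d, survival = %d%% at horizon\n",
              x$n, x$n_events, x$surv_pct))
  invisible(x)
}
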