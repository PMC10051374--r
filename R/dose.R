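#' Thermal dose specification
#'
#' Constants of the cumulative-equivalent-minutes (CEM) dose at a reference
#' temperature: `CEM = sum R^(T_ref - Tbar) * dt`, with the per-degree
#' cell-death rate constant R taking one value above and one at or below the
#' breakpoint temperature. [cem50_spec()] gives the ablative-regime dose at
#' 50 degrees C with the tabulated constants 0.51 (above 50) and 0.27 (at or
#' below); [cem43_spec()] gives the classical hyperthermia dose at 43 degrees
#' C with 0.5 / 0.25. Note that 0.51 and 0.27 are tabulated, rounded values;
#' the activation-energy power law applied to 0.5 / 0.25 gives 0.515 / 0.2652
#' (see [convert_rate_constant()]).
#'
#' @param T_ref Reference temperature in degrees C.
#' @param R_above Rate constant for interval mean temperatures above the
#'   breakpoint, in (0, 1].
#' @param R_below Rate constant at or below the breakpoint, in (0, R_above].
#' @param breakpoint Breakpoint temperature in degrees C; defaults to T_ref.
#' @return An object of class `dose_spec`.
#' @export
dose_spec <- function(T_ref, R_above, R_below, breakpoint = T_ref) {
  check_number(T_ref, "T_ref")
  check_number(R_above, "R_above", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(R_below, "R_below", lower = 0, upper = 1, strict_lower = TRUE)
  if (R_below > R_above) ptt_error("`R_below` must not exceed `R_above`")
  check_number(breakpoint, "breakpoint")
  structure(
    list(T_ref = T_ref, R_above = R_above, R_below = R_below,
         breakpoint = breakpoint),
    class = "dose_spec"
  )
}

#' @rdname dose_spec
#' @export
cem50_spec <- function() dose_spec(50, R_above = 0.51, R_below = 0.27)

#' @rdname dose_spec
#' @export
cem43_spec <- function() dose_spec(43, R_above = 0.5, R_below = 0.25)

#' Cumulative equivalent minutes of a temperature trace
#'
#' Integrates the thermal dose over the analysis window of a trace:
#' `CEM = sum over sample intervals of R^(T_ref - Tbar) * dt` with dt in
#' minutes, Tbar the mean of the two samples bounding each interval
#' (trapezoid-style), and R chosen per interval (`R_above` if Tbar exceeds
#' the breakpoint, `R_below` at or below it).
#'
#' @param trace A [temperature_trace()].
#' @param spec A [dose_spec()].
#' @param t0,t_final Optional window override in seconds; defaults to the
#'   trace's own analysis window.
#' @return Dose in equivalent minutes at `spec$T_ref` (>= 0).
#' @examples
#' tr <- temperature_trace(seq(0, 600), rep(50, 601))
#' cem(tr, cem50_spec()) # 10 minutes at the reference temperature
#' @export
cem <- function(trace, spec, t0 = NULL, t_final = NULL) {
  if (!inherits(trace, "temperature_trace")) {
    ptt_error("`trace` must be a temperature_trace")
  }
  if (!inherits(spec, "dose_spec")) ptt_error("`spec` must be a dose_spec")
  t0 <- t0 %||% trace$t0
  t_final <- t_final %||% trace$t_final
  idx <- which(trace$times >= t0 & trace$times <= t_final)
  if (length(idx) < 2L) {
    ptt_error("dose window contains fewer than two samples")
  }
  tt <- trace$times[idx]
  temp <- trace$temps[idx]
  tbar <- (temp[-1L] + temp[-length(temp)]) / 2
  R <- ifelse(tbar > spec$breakpoint, spec$R_above, spec$R_below)
  sum(R^(spec$T_ref - tbar) * diff(tt)) / 60
}

#' Convert a cell-death rate constant between reference temperatures
#'
#' Raises a CEM43 rate constant to the activation-energy exponent to obtain
#' the corresponding constant at the ablative reference (CEM50), assuming a
#' temperature-independent activation energy: `R_50 = R_43 ^ exponent` with
#' the default exponent 0.9575.
#'
#' @param R_43 Rate constant at the 43 degrees C reference, in (0, 1].
#' @param exponent Conversion exponent, > 0. Default 0.9575.
#' @return The converted rate constant.
#' @examples
#' convert_rate_constant(0.25) # 0.2652, tabulated as 0.27
#' convert_rate_constant(0.5)  # 0.5150, tabulated as 0.51
#' @export
convert_rate_constant <- function(R_43, exponent = 0.9575) {
  check_number(R_43, "R_43", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(exponent, "exponent", lower = 0, strict_lower = TRUE)
  R_43^exponent
}

#' Dose summary of a trace at several reference temperatures
#'
#' Computes each requested CEM dose directly from the trace (no scalar
#' cross-conversion between references, which is exact only for traces
#' confined to one branch of the rate constant), together with the maximum
#' temperature in the window and the time spent above each breakpoint.
#'
#' @param trace A [temperature_trace()].
#' @param specs A list of [dose_spec()] objects.
#' @return A data.frame with one row per spec: `T_ref`, `R_above`, `R_below`,
#'   `breakpoint`, `cem_min`, `time_above_breakpoint_min`, `max_temp_C`.
#' @export
dose_summary <- function(trace, specs) {
  if (inherits(specs, "dose_spec")) specs <- list(specs)
  if (!is.list(specs)) ptt_error("`specs` must be a list of dose_spec objects")
  empty <- data.frame(T_ref = numeric(0), R_above = numeric(0),
                      R_below = numeric(0), breakpoint = numeric(0),
                      cem_min = numeric(0),
                      time_above_breakpoint_min = numeric(0),
                      max_temp_C = numeric(0))
  if (length(specs) == 0L) return(empty)
  idx <- which(trace$times >= trace$t0 & trace$times <= trace$t_final)
  tt <- trace$times[idx]
  temp <- trace$temps[idx]
  tbar <- (temp[-1L] + temp[-length(temp)]) / 2
  rows <- lapply(specs, function(sp) {
    if (!inherits(sp, "dose_spec")) ptt_error("specs must be dose_spec objects")
    data.frame(
      T_ref = sp$T_ref, R_above = sp$R_above, R_below = sp$R_below,
      breakpoint = sp$breakpoint,
      cem_min = cem(trace, sp),
      time_above_breakpoint_min = sum(diff(tt)[tbar > sp$breakpoint]) / 60,
      max_temp_C = max(temp)
    )
  })
  do.call(rbind, rows)
}

#' Group summaries and pairwise comparisons of thermal doses
#'
#' Mean and standard deviation of the dose per experimental group, plus
#' two-sided Welch tests of equal means between every pair of groups with at
#' least two members, flagged for significance at the 0.05 level. Groups with
#' a single member are reported with an undefined SD and flagged.
#'
#' @param doses_by_group A named list mapping group label to a numeric vector
#'   of doses in minutes (each non-empty).
#' @param alpha Significance level for the pairwise flags. Default 0.05.
#' @return A list of class `dose_group_stats` with elements `groups`
#'   (group, n, mean, sd, sd_defined) and `pairwise` (group1, group2,
#'   statistic, df, p_value, significant).
#' @export
group_dose_stats <- function(doses_by_group, alpha = 0.05) {
  if (!is.list(doses_by_group) || is.null(names(doses_by_group)) ||
      any(names(doses_by_group) == "")) {
    ptt_error("`doses_by_group` must be a named list of numeric vectors")
  }
  if (any(vapply(doses_by_group, length, integer(1)) == 0L)) {
    ptt_error("every group must be non-empty")
  }
  groups <- data.frame(
    group = names(doses_by_group),
    n = vapply(doses_by_group, length, integer(1)),
    mean = vapply(doses_by_group, mean, numeric(1)),
    sd = vapply(doses_by_group,
                function(x) if (length(x) < 2L) NA_real_ else stats::sd(x),
                numeric(1)),
    row.names = NULL
  )
  groups$sd_defined <- !is.na(groups$sd)

  testable <- groups$group[groups$n >= 2L]
  pairwise <- data.frame(group1 = character(0), group2 = character(0),
                         statistic = numeric(0), df = numeric(0),
                         p_value = numeric(0), significant = logical(0))
  if (length(testable) >= 2L) {
    combos <- utils::combn(testable, 2L)
    rows <- apply(combos, 2L, function(pair) {
      x <- doses_by_group[[pair[1L]]]
      y <- doses_by_group[[pair[2L]]]
      tt <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
      if (is.null(tt)) {
        # degenerate (zero-variance) inputs: identical means give p = 1
        p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
        data.frame(group1 = pair[1L], group2 = pair[2L],
                   statistic = NA_real_, df = NA_real_, p_value = p,
                   significant = p < alpha)
      } else {
        data.frame(group1 = pair[1L], group2 = pair[2L],
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter),
                   p_value = tt$p.value, significant = tt$p.value < alpha)
      }
    })
    pairwise <- do.call(rbind, rows)
  }
  structure(list(groups = groups, pairwise = pairwise),
            class = "dose_group_stats")
}

#' @export
print.dose_group_stats <- function(x, ...) {
  cat("<dose_group_stats>\n")
  print(x$groups, row.names = FALSE)
  if (nrow(x$pairwise)) {
    cat("pairwise Welch tests:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
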