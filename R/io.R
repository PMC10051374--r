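# Plain-CSV readers/writers for thermal-camera traces, caliper tables and
# outcome tables. Trace files carry a commented `# key=value` metadata
# header, matching camera-export conventions.

#' Write a temperature trace to CSV
#'
#' Writes columns `time_s`, `temp_C` (and `power_W` when recorded), preceded
#' by commented `# key=value` metadata lines (`t_off_s`, `T_env_C` when
#' known). Values are written at full double precision so that a written
#' trace reads back identically.
#'
#' @param trace A [temperature_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "temperature_trace")) {
    ptt_error("`trace` must be a temperature_trace")
  }
  fmt <- function(x) sprintf("%.17g", x)
  meta <- character(0)
  if (!is.null(trace$t_off)) {
    meta <- c(meta, paste0("# t_off_s=", fmt(trace$t_off)))
  }
  if (!is.null(trace$T_env)) {
    meta <- c(meta, paste0("# T_env_C=", fmt(trace$T_env)))
  }
  has_power <- !is.null(trace$power)
  header <- if (has_power) "time_s,temp_C,power_W" else "time_s,temp_C"
  rows <- if (has_power) {
    paste(fmt(trace$times), fmt(trace$temps), fmt(trace$power), sep = ",")
  } else {
    paste(fmt(trace$times), fmt(trace$temps), sep = ",")
  }
  writeLines(c(meta, header, rows), path)
  invisible(path)
}

#' Read a temperature trace from CSV
#'
#' Parses a trace CSV with optional `# key=value` metadata header lines
#' (recognized keys: `t_off_s`, `T_env_C`). Malformed or non-monotone rows
#' are reported with their file line numbers.
#'
#' @param path Input file path.
#' @return A [temperature_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    ptt_error(sprintf("file not found: %s", path),
              class = "pttdose_format_error")
  }
  lines <- readLines(path, warn = FALSE)
  is_meta <- startsWith(trimws(lines), "#")
  meta_lines <- lines[is_meta]
  body <- lines[!is_meta & nzchar(trimws(lines))]
  body_lineno <- which(!is_meta & nzchar(trimws(lines)))
  if (length(body) < 2L) {
    ptt_error(sprintf("%s: no data rows", path),
              class = "pttdose_format_error")
  }

  meta <- list()
  for (m in meta_lines) {
    kv <- strsplit(sub("^\\s*#\\s*", "", m), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- as.numeric(trimws(kv[2L]))
  }

  dat <- utils::read.csv(text = paste(body, collapse = "\n"),
                         stringsAsFactors = FALSE)
  num_cols <- intersect(c("time_s", "temp_C", "power_W"), names(dat))
  dat[num_cols] <- lapply(dat[num_cols], function(x) {
    if (is.double(x)) x else as.numeric(as.character(x))
  })
  if (!all(c("time_s", "temp_C") %in% names(dat))) {
    ptt_error(sprintf("%s: missing required columns time_s, temp_C", path),
              class = "pttdose_format_error")
  }
  bad <- which(!is.finite(dat$time_s) | !is.finite(dat$temp_C))
  if (length(bad) > 0L) {
    ptt_error(sprintf("%s: malformed value on line %d", path,
                      body_lineno[bad[1L] + 1L]),
              class = "pttdose_format_error")
  }
  nonmono <- which(diff(dat$time_s) <= 0)
  if (length(nonmono) > 0L) {
    ptt_error(sprintf(
      "%s: time not strictly increasing at line %d", path,
      body_lineno[nonmono[1L] + 2L]), class = "pttdose_format_error")
  }
  temperature_trace(
    dat$time_s, dat$temp_C,
    power = if ("power_W" %in% names(dat)) dat$power_W else NULL,
    t_off = meta[["t_off_s"]],
    T_env = meta[["T_env_C"]]
  )
}

#' Read and write caliper measurement tables
#'
#' Caliper CSVs have columns `animal_id`, `group`, `day`, `D_mm`, `d_mm`;
#' outcome CSVs have `animal_id`, `event` (none/death/sacrifice) and
#' `event_day`.
#'
#' @param path File path.
#' @return `read_caliper()` and `read_outcomes()` return data.frames.
#' @export
read_caliper <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "day", "D_mm", "d_mm")
  if (!all(need %in% names(dat))) {
    ptt_error(sprintf("%s: caliper table needs columns %s", path,
                      paste(need, collapse = ", ")),
              class = "pttdose_format_error")
  }
  dat
}

#' @rdname read_caliper
#' @export
read_outcomes <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "event", "event_day")
  if (!all(need %in% names(dat))) {
    ptt_error(sprintf("%s: outcome table needs columns %s", path,
                      paste(need, collapse = ", ")),
              class = "pttdose_format_error")
  }
  dat
}

#' Assemble animal records from caliper and outcome tables
#'
#' @param caliper A caliper data.frame (see [read_caliper()]).
#' @param outcomes Optional outcome data.frame; animals absent from it are
#'   treated as alive through follow-up.
#' @param followup_end Follow-up horizon in days.
#' @return A named list of [animal_record()] objects.
#' @export
caliper_to_records <- function(caliper, outcomes = NULL, followup_end = 120) {
  ids <- unique(c(caliper$animal_id,
                  if (!is.null(outcomes)) outcomes$animal_id))
  records <- lapply(ids, function(id) {
    rows <- caliper[caliper$animal_id == id, , drop = FALSE]
    group <- if (nrow(rows)) rows$group[1L] else "unknown"
    meas <- data.frame(day = rows$day, D_mm = rows$D_mm, d_mm = rows$d_mm)
    event <- "none"
    event_day <- NA_real_
    if (!is.null(outcomes)) {
      o <- outcomes[outcomes$animal_id == id, , drop = FALSE]
      if (nrow(o) > 0L && o$event[1L] != "none") {
        event <- o$event[1L]
        event_day <- o$event_day[1L]
      }
    }
    animal_record(id, group, meas, event = event, event_day = event_day,
                  followup_end = followup_end)
  })
  names(records) <- ids
  records
}

#' Write the caliper and outcome tables of a cohort
#'
#' @param records A list of [animal_record()] objects.
#' @param caliper_path,outcomes_path Output CSV paths.
#' @return Invisibly, a list of the written paths.
#' @export
write_cohort_tables <- function(records, caliper_path, outcomes_path) {
  cal <- do.call(rbind, lapply(records, function(r) {
    if (nrow(r$measurements) == 0L) return(NULL)
    data.frame(animal_id = r$animal_id, group = r$group,
               day = r$measurements$day, D_mm = r$measurements$D_mm,
               d_mm = r$measurements$d_mm)
  }))
  out <- do.call(rbind, lapply(records, function(r) {
    data.frame(animal_id = r$animal_id, event = r$event,
               event_day = r$event_day)
  }))
  utils::write.csv(cal, caliper_path, row.names = FALSE)
  utils::write.csv(out, outcomes_path, row.names = FALSE)
  invisible(list(caliper = caliper_path, outcomes = outcomes_path))
}
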