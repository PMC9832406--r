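# Delimited-text formats: patients file, capacity file, schedule file.
# Comma-delimited UTF-8 with a header row is the canonical dialect.

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_validation("%s: missing required column(s): %s",
                    path, paste(miss, collapse = ", "))
  }
  df
}

# data line number in the file (header is line 1)
line_no <- function(i) i + 1L

#' Read a patients file
#'
#' Expects comma-delimited text with header
#' `patient_id, rtt_weeks, risk_category, dist_<clinic>...` (at least one
#' `dist_` column).  Malformed rows are rejected with their line number.
#'
#' @param path file path.
#' @return A patients data frame for [sched_instance()].
#' @export
read_patients <- function(path) {
  df <- read_table_checked(path, c("patient_id", "rtt_weeks", "risk_category"))
  dcols <- grep("^dist_", names(df), value = TRUE)
  if (!length(dcols)) {
    stop_validation("%s: needs at least one dist_<clinic> column", path)
  }
  df$patient_id <- as.character(df$patient_id)
  dup <- which(duplicated(df$patient_id))
  if (length(dup)) {
    stop_validation("%s: line %d: duplicate patient_id '%s'",
                    path, line_no(dup[1L]), df$patient_id[dup[1L]])
  }
  rtt <- suppressWarnings(as.numeric(df$rtt_weeks))
  bad <- which(is.na(rtt) | rtt < 0)
  if (length(bad)) {
    stop_validation("%s: line %d: rtt_weeks '%s' is not a non-negative number",
                    path, line_no(bad[1L]), df$rtt_weeks[bad[1L]])
  }
  df$rtt_weeks <- rtt
  bad <- which(!(df$risk_category %in% RISK_CATEGORIES))
  if (length(bad)) {
    stop_validation("%s: line %d: risk_category '%s' must be one of %s",
                    path, line_no(bad[1L]), df$risk_category[bad[1L]],
                    paste(RISK_CATEGORIES, collapse = ", "))
  }
  for (col in dcols) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x))
    if (length(bad)) {
      stop_validation("%s: line %d: %s '%s' is not a number",
                      path, line_no(bad[1L]), col, df[[col]][bad[1L]])
    }
    df[[col]] <- x
  }
  df[, c("patient_id", "rtt_weeks", "risk_category", dcols)]
}

#' Write a patients file
#' @param patients a patients data frame (e.g. from [generate_cohort()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  utils::write.csv(patients, path, row.names = FALSE)
  invisible(path)
}

#' Read a capacity file
#'
#' Long-format comma-delimited text with header `clinic, day, capacity`
#' (1-based integer days, non-negative integer capacities, no duplicate
#' clinic-day pairs).  Clinic-day pairs not listed get capacity 0; the
#' horizon runs to the largest day seen (or `horizon_days`).
#'
#' @param path file path.
#' @param horizon_days optional explicit horizon length.
#' @return A [capacity_calendar()].
#' @export
read_capacity <- function(path, horizon_days = NULL) {
  df <- read_table_checked(path, c("clinic", "day", "capacity"))
  day <- suppressWarnings(as.numeric(df$day))
  bad <- which(is.na(day) | day < 1 | day != round(day))
  if (length(bad)) {
    stop_validation("%s: line %d: day '%s' must be a positive integer",
                    path, line_no(bad[1L]), df$day[bad[1L]])
  }
  capv <- suppressWarnings(as.numeric(df$capacity))
  bad <- which(is.na(capv) | capv < 0 | capv != round(capv))
  if (length(bad)) {
    stop_validation("%s: line %d: capacity '%s' must be a non-negative integer",
                    path, line_no(bad[1L]), df$capacity[bad[1L]])
  }
  key <- paste(df$clinic, day)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_validation("%s: line %d: duplicate (clinic, day) entry (%s, %s)",
                    path, line_no(dup[1L]), df$clinic[dup[1L]], day[dup[1L]])
  }
  capacity_calendar(data.frame(clinic = as.character(df$clinic),
                               day = as.integer(day),
                               capacity = as.integer(capv),
                               stringsAsFactors = FALSE),
                    horizon_days = horizon_days)
}

#' Write a capacity file
#' @param calendar a [capacity_calendar()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_capacity <- function(calendar, path) {
  stopifnot(inherits(calendar, "capacity_calendar"))
  long <- data.frame(
    clinic = rep(calendar$locations, times = calendar$horizon_days),
    day = rep(seq_len(calendar$horizon_days), each = length(calendar$locations)),
    capacity = as.integer(calendar$capacity[cbind(
      rep(seq_along(calendar$locations), times = calendar$horizon_days),
      rep(seq_len(calendar$horizon_days), each = length(calendar$locations)))]),
    stringsAsFactors = FALSE)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Write a schedule file
#'
#' One row per input patient (input order), header
#' `patient_id, status, clinic, day`; `clinic` and `day` are empty for
#' unscheduled patients.
#'
#' @param path output path.
#' @param instance the [sched_instance()] the schedule was solved on.
#' @param schedule the schedule to export.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(path, instance, schedule) {
  a <- schedule$assignments
  idx <- match(instance$patients$patient_id, a$patient_id)
  out <- data.frame(
    patient_id = instance$patients$patient_id,
    status = ifelse(is.na(idx), "unscheduled", "scheduled"),
    clinic = ifelse(is.na(idx), "", a$clinic[idx]),
    day = ifelse(is.na(idx), "", as.character(a$day[idx])),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a schedule file
#' @param path a file written by [write_schedule()].
#' @return Data frame with `patient_id`, `status`, `clinic`, `day`
#'   (`NA` clinic/day for unscheduled rows).
#' @export
read_schedule <- function(path) {
  df <- read_table_checked(path, c("patient_id", "status", "clinic", "day"))
  bad <- which(!(df$status %in% c("scheduled", "unscheduled")))
  if (length(bad)) {
    stop_validation("%s: line %d: status '%s' must be scheduled or unscheduled",
                    path, line_no(bad[1L]), df$status[bad[1L]])
  }
  sched <- df$status == "scheduled"
  incomplete <- which(sched & (is.na(df$day) | df$clinic == "" | df$clinic %in% NA))
  if (length(incomplete)) {
    stop_validation("%s: line %d: scheduled row needs both clinic and day",
                    path, line_no(incomplete[1L]))
  }
  data.frame(patient_id = as.character(df$patient_id),
             status = df$status,
             clinic = ifelse(sched, as.character(df$clinic), NA_character_),
             day = ifelse(sched, suppressWarnings(as.integer(df$day)), NA_integer_),
             stringsAsFactors = FALSE)
}

#' Write a metrics report
#' @param report a [compute_metrics()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  df <- as.data.frame(unclass(report))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
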