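# Performance report for a schedule and the seven-objective sweep.

#' Performance metrics for a schedule
#'
#' Summarizes a feasible schedule the way the tool's report sheet does.
#' The unscheduled count is `P - sum_{p,l,t} x_{p,l,t}`; the remaining RTT
#' and risk sums are the sum-products of the not-scheduled indicator with
#' the per-patient RTT and risk score; the scheduled totals are the
#' corresponding sum-products over the realized assignments (the distance
#' total uses each patient's score at the clinic they were booked into).
#' Conservation holds by construction: scheduled + remaining totals equal
#' the cohort totals, and scheduled + unscheduled counts equal P.
#'
#' @param instance a [sched_instance()].
#' @param schedule a feasible schedule for the instance; an infeasible one
#'   raises an error listing every violation.
#' @return A list of class `"metrics_report"` with fields
#'   `total_rtt_scheduled`, `total_distance_scheduled`,
#'   `total_risk_scheduled`, `n_scheduled`, `remaining_rtt_unscheduled`,
#'   `remaining_risk_unscheduled`, `n_unscheduled` and
#'   `mean_rtt_per_scheduled` (unrounded; see [mean_rtt()] for the
#'   2-decimal presentation form).
#' @examples
#' inst <- case_study_instance(seed = 1)
#' compute_metrics(inst, solve_schedule(inst, objective_spec("R")))
#' @export
compute_metrics <- function(instance, schedule) {
  stop_if_invalid(instance)
  v <- check_feasibility(instance, schedule)
  if (length(v)) {
    stop_validation("schedule is infeasible:\n%s", paste("  -", v, collapse = "\n"))
  }
  p <- instance$patients
  a <- schedule$assignments
  sched <- p$patient_id %in% a$patient_id
  risk_score <- as.numeric(instance$risk_weights[p$risk_category])
  D <- distance_matrix(instance)
  dist_total <- if (nrow(a)) {
    sum(D[cbind(match(a$patient_id, p$patient_id),
                match(a$clinic, instance$calendar$locations))])
  } else 0
  n_s <- sum(sched)
  r <- list(
    total_rtt_scheduled = sum(p$rtt_weeks[sched]),
    total_distance_scheduled = dist_total,
    total_risk_scheduled = sum(risk_score[sched]),
    n_scheduled = n_s,
    remaining_rtt_unscheduled = sum(p$rtt_weeks[!sched]),
    remaining_risk_unscheduled = sum(risk_score[!sched]),
    n_unscheduled = nrow(p) - n_s,
    mean_rtt_per_scheduled = if (n_s > 0) sum(p$rtt_weeks[sched]) / n_s else NA_real_)
  structure(r, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Schedule metrics:\n")
  cat(sprintf("  scheduled:   %d patients | RTT %s wk | distance %s | risk %s\n",
              x$n_scheduled, format(x$total_rtt_scheduled, big.mark = ","),
              format(x$total_distance_scheduled, big.mark = ","),
              format(x$total_risk_scheduled, big.mark = ",")))
  cat(sprintf("  unscheduled: %d patients | remaining RTT %s wk | remaining risk %s\n",
              x$n_unscheduled, format(x$remaining_rtt_unscheduled, big.mark = ","),
              format(x$remaining_risk_unscheduled, big.mark = ",")))
  if (x$n_scheduled > 0) {
    cat(sprintf("  mean RTT per scheduled patient: %.2f wk\n",
                x$mean_rtt_per_scheduled))
  }
  invisible(x)
}

#' Mean RTT per scheduled patient
#'
#' Presentation helper: the quotient of total scheduled RTT by the number
#' of scheduled patients, rounded to two decimals for reporting (the exact
#' quotient is kept in the `"exact"` attribute).  E.g. a total of 8746
#' weeks across 329 patients averages 26.58 weeks per patient.
#'
#' @param total_rtt total RTT (weeks) over the scheduled patients.
#' @param n_scheduled number of scheduled patients; must be positive.
#' @return The rounded mean (numeric), with attribute `"exact"`.
#' @export
mean_rtt <- function(total_rtt, n_scheduled) {
  if (!is_count(n_scheduled) || n_scheduled == 0) {
    stop_validation("mean RTT is undefined for n_scheduled = 0")
  }
  exact <- total_rtt / n_scheduled
  structure(round(exact, 2), exact = exact)
}

#' Solve an instance under all seven named objectives
#'
#' Runs [solve_schedule()] for each label in [objective_labels()] (in the
#' canonical order RTT, D, R, RTT+D, D+R, RTT+R, RTT+D+R) and tabulates
#' the [compute_metrics()] report of each optimum.
#'
#' @param instance a valid [sched_instance()].
#' @param options a [solver_options()].
#' @return A data frame of class `"objective_sweep"`, one row per label,
#'   with column `objective` followed by the metrics-report fields.
#' @seealso [write_sweep()] for the delimited export with report-style
#'   column headers.
#' @export
objective_sweep <- function(instance, options = solver_options()) {
  stop_if_invalid(instance)
  rows <- lapply(SWEEP_LABELS, function(lbl) {
    rep_ <- tryCatch(
      compute_metrics(instance,
                      solve_schedule(instance, objective_spec(lbl), options)),
      error = function(e) {
        stop(errorCondition(
          sprintf("sweep failed at objective '%s': %s", lbl, conditionMessage(e)),
          class = class(e)))
      })
    data.frame(objective = lbl,
               total_rtt_scheduled = rep_$total_rtt_scheduled,
               total_distance_scheduled = rep_$total_distance_scheduled,
               total_risk_scheduled = rep_$total_risk_scheduled,
               n_scheduled = rep_$n_scheduled,
               remaining_rtt_unscheduled = rep_$remaining_rtt_unscheduled,
               remaining_risk_unscheduled = rep_$remaining_risk_unscheduled,
               n_unscheduled = rep_$n_unscheduled,
               mean_rtt_per_scheduled = rep_$mean_rtt_per_scheduled,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("objective_sweep", "data.frame")
  out
}

SWEEP_HEADERS <- c(
  "Objective",
  "Total number of weeks from referral to treatment (RTT objective)",
  "Total distance score (distance objective)",
  "Total risk (risk-objective)",
  "Number of patients scheduled",
  "Sum of remaining RTT for patients that were not scheduled",
  "Sum of remaining risk score for patients that were not scheduled",
  "Number of patients not scheduled")

#' Export an objective sweep as delimited text
#'
#' Writes the sweep table as comma-separated UTF-8 with the report-style
#' column headers used in the tool's outcome sheet.
#'
#' @param sweep an [objective_sweep()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "objective_sweep"))
  out <- sweep[, c("objective", "total_rtt_scheduled",
                   "total_distance_scheduled", "total_risk_scheduled",
                   "n_scheduled", "remaining_rtt_unscheduled",
                   "remaining_risk_unscheduled", "n_unscheduled")]
  names(out) <- SWEEP_HEADERS
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
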