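# Rolling-horizon deployment: collect new referrals each period, re-solve
# over a fresh calendar window, notify the scheduled patients, and carry
# the rest forward with aged RTT.

#' Arrival stream for rolling-horizon simulation
#'
#' @param n_periods number of re-optimization periods to simulate.
#' @param period_length_days days between consecutive solves (1 = nightly
#'   batching of the day's referrals, 7 = weekly).
#' @param arrivals_per_period expected (or exact) number of new referrals
#'   per period.
#' @param distribution `"constant"` for exactly `arrivals_per_period`
#'   arrivals each period, `"poisson"` for Poisson-distributed counts with
#'   that mean.
#' @param cohort a [cohort_spec()] template describing how new referrals
#'   look (risk mix, RTT at arrival, distance bounds); its `n_patients`
#'   and `seed` are overridden per period.
#' @param seed integer seed governing both arrival counts and the arriving
#'   patients' attributes.
#' @return A list of class `"arrival_stream"`.
#' @export
arrival_stream <- function(n_periods, period_length_days = 7L,
                           arrivals_per_period = 10L,
                           distribution = c("constant", "poisson"),
                           cohort = cohort_spec(1L),
                           seed = 1L) {
  distribution <- match.arg(distribution)
  if (!is_count(n_periods) || n_periods < 1) stop_validation("n_periods must be >= 1")
  if (!is_count(period_length_days) || period_length_days < 1) {
    stop_validation("period_length_days must be >= 1")
  }
  if (!is.numeric(arrivals_per_period) || arrivals_per_period < 0) {
    stop_validation("arrivals_per_period must be non-negative")
  }
  stopifnot(inherits(cohort, "cohort_spec"))
  structure(list(n_periods = as.integer(n_periods),
                 period_length_days = as.integer(period_length_days),
                 arrivals_per_period = arrivals_per_period,
                 distribution = distribution,
                 cohort = cohort,
                 seed = as.integer(seed)),
            class = "arrival_stream")
}

#' Rolling-horizon re-optimization
#'
#' Simulates running the scheduler repeatedly as a live booking process.
#' Each period k: (1) the current waiting list is solved against a fresh
#' copy of the calendar window (stationary capacity -- unfilled slots
#' expire rather than roll forward); (2) scheduled patients leave the
#' list; (3) the survivors' RTT ages by `period_length_days / 7` weeks;
#' (4) the period's new referrals join the list.  Deterministic given the
#' stream seed.
#'
#' @param initial a [sched_instance()] holding the opening waiting list,
#'   the calendar window reused every period, and the risk weighting.
#' @param stream an [arrival_stream()].
#' @param objective an [objective_spec()].
#' @param options a [solver_options()].
#' @return A list of class `"rolling_result"`: `periods` (per period:
#'   `schedule`, `report`, `n_arrivals`), `final_waiting` (patients data
#'   frame), and `waits` -- one row per patient ever seen, with
#'   `arrival_period` (0 for the opening list), `scheduled_period` (NA if
#'   still waiting) and `wait_periods`.
#' @examples
#' inst <- sched_instance(generate_cohort(cohort_spec(20, seed = 3)),
#'                        generate_calendar(calendar_spec(total_capacity = 12)))
#' rr <- rolling_run(inst, arrival_stream(3, cohort = cohort_spec(1L, seed = 1),
#'                                        arrivals_per_period = 5, seed = 9),
#'                   objective_spec("RTT+D+R"))
#' rr$waits[1:3, ]
#' @export
rolling_run <- function(initial, stream, objective,
                        options = solver_options()) {
  stop_if_invalid(initial)
  stopifnot(inherits(stream, "arrival_stream"),
            inherits(objective, "objective_spec"),
            inherits(options, "solver_options"))
  waiting <- initial$patients
  calendar <- initial$calendar
  rw <- initial$risk_weights
  aging <- stream$period_length_days / 7

  n_arr <- with_seed(stream$seed, {
    if (stream$distribution == "constant") {
      rep(as.integer(round(stream$arrivals_per_period)), stream$n_periods)
    } else {
      rpois(stream$n_periods, stream$arrivals_per_period)
    }
  })

  waits <- data.frame(patient_id = waiting$patient_id,
                      arrival_period = rep(0L, nrow(waiting)),
                      scheduled_period = rep(NA_integer_, nrow(waiting)),
                      stringsAsFactors = FALSE)
  periods <- vector("list", stream$n_periods)

  for (k in seq_len(stream$n_periods)) {
    inst_k <- sched_instance(waiting, calendar, rw)
    sch <- tryCatch(solve_schedule(inst_k, objective, options),
                    error = function(e) {
                      stop(errorCondition(
                        sprintf("period %d: %s", k, conditionMessage(e)),
                        class = class(e)))
                    })
    rep_k <- compute_metrics(inst_k, sch)
    got <- waiting$patient_id %in% sch$assignments$patient_id
    waits$scheduled_period[match(waiting$patient_id[got], waits$patient_id)] <- k
    periods[[k]] <- list(schedule = sch, report = rep_k, n_arrivals = n_arr[k])

    # carry-over: survivors age by one period before the next solve
    waiting <- waiting[!got, , drop = FALSE]
    waiting$rtt_weeks <- waiting$rtt_weeks + aging

    if (n_arr[k] > 0L) {
      cs <- stream$cohort
      cs$n_patients <- n_arr[k]
      cs$as_counts <- FALSE   # per-period counts vary; use mix probabilities
      if (sum(cs$risk_composition) > 1.5) {
        cs$risk_composition <- cs$risk_composition / sum(cs$risk_composition)
      }
      cs$locations <- calendar$locations
      cs$seed <- (stream$seed + 7919L * k) %% .Machine$integer.max
      arr <- generate_cohort(cs)
      arr$patient_id <- sprintf("A%02d_%s", k, arr$patient_id)
      waiting <- rbind(waiting, arr[, names(waiting)])
      waits <- rbind(waits, data.frame(patient_id = arr$patient_id,
                                       arrival_period = k,
                                       scheduled_period = NA_integer_,
                                       stringsAsFactors = FALSE))
    }
    rownames(waiting) <- NULL
  }
  waits$wait_periods <- ifelse(is.na(waits$scheduled_period), NA_integer_,
                               waits$scheduled_period - waits$arrival_period)
  structure(list(periods = periods, final_waiting = waiting, waits = waits),
            class = "rolling_result")
}

#' @export
print.rolling_result <- function(x, ...) {
  n_sched <- sum(!is.na(x$waits$scheduled_period))
  cat(sprintf("Rolling-horizon run: %d period(s), %d patients scheduled, %d still waiting\n",
              length(x$periods), n_sched, nrow(x$final_waiting)))
  if (n_sched) {
    cat(sprintf("  mean realized wait: %.2f period(s)\n",
                mean(x$waits$wait_periods, na.rm = TRUE)))
  }
  invisible(x)
}

#' Longitudinal summary of a rolling run
#'
#' @param result a [rolling_run()] result.
#' @return Data frame with one row per period: arrivals, list size at
#'   solve time, scheduled and carried-over counts, and the period's
#'   scheduled-total metrics.
#' @export
rolling_summary <- function(result) {
  stopifnot(inherits(result, "rolling_result"))
  do.call(rbind, lapply(seq_along(result$periods), function(k) {
    p <- result$periods[[k]]
    r <- p$report
    data.frame(period = k,
               waiting_at_solve = r$n_scheduled + r$n_unscheduled,
               scheduled = r$n_scheduled,
               carried_over = r$n_unscheduled,
               arrivals_after = p$n_arrivals,
               total_rtt_scheduled = r$total_rtt_scheduled,
               total_risk_scheduled = r$total_risk_scheduled,
               total_distance_scheduled = r$total_distance_scheduled)
  }))
}
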