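# Core domain types: patients, risk weightings, capacity calendars,
# scheduling instances and objective specifications.

RISK_CATEGORIES <- c("R1", "R2", "R3")

#' Risk-category weighting
#'
#' Maps the three clinical risk categories to positive scores. Higher
#' clinical risk must receive a strictly higher score: R1 ("risk of
#' irreversible harm or significant adverse outcome if the target date is
#' missed") > R2 ("risk of reversible harm") > R3 ("no significant risk").
#' The default 1000/10/1 gives R1 numerical dominance over any realistic
#' RTT (weeks) or distance score (at most 50), so that under any objective
#' containing the risk term no R1 patient is displaced by lower-risk
#' patients.
#'
#' @param R1,R2,R3 positive scores with `R1 > R2 > R3 > 0`.
#' @return A named numeric vector of length 3, class `"risk_weights"`.
#' @examples
#' risk_weights()            # 1000/10/1 default
#' risk_weights(500, 50, 5)  # custom, still strictly decreasing
#' @export
risk_weights <- function(R1 = 1000, R2 = 10, R3 = 1) {
  w <- c(R1 = as.numeric(R1), R2 = as.numeric(R2), R3 = as.numeric(R3))
  if (!all(vapply(w, is_number, TRUE))) {
    stop_validation("risk weights must be finite numbers")
  }
  if (!(w[["R1"]] > w[["R2"]] && w[["R2"]] > w[["R3"]] && w[["R3"]] > 0)) {
    stop_validation(
      "risk weights must satisfy R1 > R2 > R3 > 0 (got %s/%s/%s)",
      w[["R1"]], w[["R2"]], w[["R3"]])
  }
  structure(w, class = "risk_weights")
}

#' Capacity calendar
#'
#' The number of bookable appointment slots per clinic per day across the
#' planning horizon, days indexed 1..T.
#'
#' @param capacity either an `L x T` matrix of non-negative integers with
#'   one row per clinic (row names become the clinic ids), or a long-format
#'   data frame with columns `clinic`, `day`, `capacity`.  Clinic-day pairs
#'   absent from a long-format table get capacity 0.
#' @param locations clinic ids; required for a matrix without row names.
#' @param horizon_days number of days T; defaults to the number of matrix
#'   columns or the maximum `day` seen.
#' @return An object of class `"capacity_calendar"`: a list with elements
#'   `locations`, `horizon_days` and the `L x T` integer `capacity` matrix.
#' @examples
#' capacity_calendar(matrix(2, 2, 5, dimnames = list(c("A", "B"), NULL)))
#' @export
capacity_calendar <- function(capacity, locations = NULL, horizon_days = NULL) {
  if (is.data.frame(capacity)) {
    need <- c("clinic", "day", "capacity")
    if (!all(need %in% names(capacity))) {
      stop_validation("long-format capacity needs columns %s",
                      paste(need, collapse = ", "))
    }
    df <- capacity
    if (anyDuplicated(df[, c("clinic", "day")])) {
      dup <- df[duplicated(df[, c("clinic", "day")]), , drop = FALSE][1L, ]
      stop_validation("duplicate capacity entry for clinic '%s', day %s",
                      dup$clinic, dup$day)
    }
    if (any(df$day < 1 | df$day != round(df$day))) {
      stop_validation("capacity days must be positive integers (1-based)")
    }
    if (is.null(locations)) locations <- unique(as.character(df$clinic))
    if (is.null(horizon_days)) horizon_days <- max(df$day)
    mat <- matrix(0L, length(locations), horizon_days,
                  dimnames = list(locations, NULL))
    unknown <- setdiff(as.character(df$clinic), locations)
    if (length(unknown)) {
      stop_validation("capacity rows reference unknown clinic(s): %s",
                      paste(unknown, collapse = ", "))
    }
    mat[cbind(match(as.character(df$clinic), locations), df$day)] <-
      as.integer(df$capacity)
    capacity <- mat
  } else {
    capacity <- as.matrix(capacity)
    if (is.null(locations)) locations <- rownames(capacity)
    if (is.null(locations)) {
      stop_validation("matrix capacity needs row names or `locations`")
    }
    rownames(capacity) <- locations
    if (is.null(horizon_days)) horizon_days <- ncol(capacity)
  }
  if (nrow(capacity) != length(locations) || ncol(capacity) != horizon_days) {
    stop_validation("capacity must be %d x %d", length(locations), horizon_days)
  }
  storage.mode(capacity) <- "integer"
  if (anyNA(capacity) || any(capacity < 0)) {
    stop_validation("capacities must be non-negative integers for every (clinic, day)")
  }
  if (anyDuplicated(locations)) stop_validation("duplicate clinic ids")
  structure(list(locations = as.character(locations),
                 horizon_days = as.integer(horizon_days),
                 capacity = capacity),
            class = "capacity_calendar")
}

#' Total slot capacity of a calendar
#' @param calendar a [capacity_calendar()].
#' @return Integer: the sum of all per-clinic per-day capacities.
#' @export
total_capacity <- function(calendar) {
  stopifnot(inherits(calendar, "capacity_calendar"))
  sum(calendar$capacity)
}

#' @export
print.capacity_calendar <- function(x, ...) {
  cat(sprintf("Capacity calendar: %d clinic(s) x %d day(s), %d slots total\n",
              length(x$locations), x$horizon_days, total_capacity(x)))
  cat("  per-clinic totals:",
      paste(sprintf("%s=%d", x$locations, rowSums(x$capacity)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Scheduling instance
#'
#' Bundles a patient waiting list, a capacity calendar and a risk weighting
#' into the unit on which the solver operates.
#'
#' @param patients a data frame with one row per patient and columns
#'   `patient_id` (unique), `rtt_weeks` (non-negative, weeks since
#'   referral), `risk_category` (`"R1"`, `"R2"` or `"R3"`), and one
#'   `dist_<clinic>` column per clinic in the calendar holding that
#'   patient's distance score for the clinic (higher = closer).
#' @param calendar a [capacity_calendar()].
#' @param risk_weights a [risk_weights()] vector.
#' @return An object of class `"sched_instance"`.
#' @seealso [validate_instance()], [generate_cohort()], [case_study_instance()]
#' @export
sched_instance <- function(patients, calendar, risk_weights = clinicsched::risk_weights()) {
  stopifnot(is.data.frame(patients), inherits(calendar, "capacity_calendar"))
  if (!inherits(risk_weights, "risk_weights")) {
    risk_weights <- do.call(clinicsched::risk_weights, as.list(risk_weights))
  }
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  if ("patient_id" %in% names(patients)) {
    patients$patient_id <- as.character(patients$patient_id)
  }
  inst <- structure(list(patients = patients,
                         calendar = calendar,
                         risk_weights = risk_weights),
                    class = "sched_instance")
  inst
}

#' @export
print.sched_instance <- function(x, ...) {
  mix <- table(factor(x$patients$risk_category, levels = RISK_CATEGORIES))
  cat(sprintf("Scheduling instance: %d patients (%s), %d clinic(s), %d day horizon, %d slots\n",
              nrow(x$patients),
              paste(sprintf("%s=%d", names(mix), as.integer(mix)), collapse = " "),
              length(x$calendar$locations), x$calendar$horizon_days,
              total_capacity(x$calendar)))
  invisible(x)
}

dist_cols <- function(locations) paste0("dist_", locations)

# P x L matrix of distance scores, rows in patient order, cols in calendar
# location order.  Assumes the instance has been validated.
distance_matrix <- function(instance) {
  locs <- instance$calendar$locations
  m <- as.matrix(instance$patients[, dist_cols(locs), drop = FALSE])
  dimnames(m) <- list(instance$patients$patient_id, locs)
  m
}

#' Validate a scheduling instance
#'
#' Checks every structural invariant of the instance and returns the
#' violations as a character vector (empty when the instance is
#' well-formed).  Violations are reported, not thrown, so callers can
#' present all problems at once; [solve_schedule()] refuses instances with
#' a non-empty result.
#'
#' Checked: required patient columns; unique patient ids; finite
#' non-negative RTT; risk categories within R1/R2/R3; exactly one finite
#' distance score per calendar clinic per patient (a `dist_` column for a
#' clinic not in the calendar is a violation too); non-negative integer
#' capacities for every (clinic, day).
#'
#' @param instance a [sched_instance()].
#' @return Character vector of human-readable violation descriptions.
#' @examples
#' inst <- case_study_instance(seed = 1)
#' validate_instance(inst)   # character(0)
#' @export
validate_instance <- function(instance) {
  v <- character()
  if (!inherits(instance, "sched_instance")) {
    return("not a sched_instance object")
  }
  p <- instance$patients
  locs <- instance$calendar$locations
  need <- c("patient_id", "rtt_weeks", "risk_category")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    return(sprintf("patients table is missing column(s): %s",
                   paste(miss, collapse = ", ")))
  }
  dup <- unique(p$patient_id[duplicated(p$patient_id)])
  for (id in dup) v <- c(v, sprintf("duplicate patient id '%s'", id))
  bad_rtt <- which(!is.finite(p$rtt_weeks) | p$rtt_weeks < 0)
  for (i in bad_rtt) {
    v <- c(v, sprintf("patient '%s': rtt_weeks must be a finite non-negative number",
                      p$patient_id[i]))
  }
  bad_risk <- which(!(p$risk_category %in% RISK_CATEGORIES))
  for (i in bad_risk) {
    v <- c(v, sprintf("patient '%s': risk_category '%s' not one of %s",
                      p$patient_id[i], p$risk_category[i],
                      paste(RISK_CATEGORIES, collapse = "/")))
  }
  for (loc in locs) {
    col <- paste0("dist_", loc)
    if (!col %in% names(p)) {
      v <- c(v, sprintf("missing distance column '%s' for clinic '%s'", col, loc))
      next
    }
    bad <- which(!is.finite(p[[col]]))
    for (i in bad) {
      v <- c(v, sprintf("patient '%s': no finite distance score for clinic '%s'",
                        p$patient_id[i], loc))
    }
  }
  extra <- setdiff(grep("^dist_", names(p), value = TRUE), dist_cols(locs))
  for (col in extra) {
    v <- c(v, sprintf("distance column '%s' refers to a clinic not in the calendar",
                      col))
  }
  cap <- instance$calendar$capacity
  if (anyNA(cap) || any(cap < 0)) {
    v <- c(v, "calendar has missing or negative capacities")
  }
  v
}

stop_if_invalid <- function(instance) {
  v <- validate_instance(instance)
  if (length(v)) {
    stop_validation("invalid instance:\n%s", paste("  -", v, collapse = "\n"))
  }
  invisible(instance)
}

# ---------------------------------------------------------------------------
# Objective specification

SWEEP_LABELS <- c("RTT", "D", "R", "RTT+D", "D+R", "RTT+R", "RTT+D+R")

label_weights <- function(label) {
  parts <- strsplit(label, "+", fixed = TRUE)[[1L]]
  c(w_rtt  = as.numeric("RTT" %in% parts),
    w_dist = as.numeric("D" %in% parts),
    w_risk = as.numeric("R" %in% parts))
}

#' The seven named objective combinations
#'
#' Individual objectives and their unweighted sums, in the canonical sweep
#' order: RTT, D, R, RTT+D, D+R, RTT+R, RTT+D+R.
#' @return Character vector of the seven labels.
#' @export
objective_labels <- function() SWEEP_LABELS

#' Objective specification
#'
#' Selects which weighted sum of the three base objectives (total RTT of
#' scheduled patients, total distance score at the assigned clinics, total
#' risk score) the solver maximizes.  A named label picks one of the seven
#' 0/1 combinations (e.g. `"RTT+D"` is weights (1, 1, 0)); arbitrary
#' non-negative weights select a custom trade-off, e.g. a health board that
#' values risk above RTT above distance.
#'
#' @param label one of [objective_labels()], or `"custom"` when `weights`
#'   are supplied.  Matching is case-insensitive (`"rtt+d"` works).
#' @param weights optional numeric vector `c(w_rtt, w_dist, w_risk)` (or
#'   named); all non-negative, at least one strictly positive.  Mutually
#'   exclusive with a non-custom `label`.
#' @return An object of class `"objective_spec"` with fields `w_rtt`,
#'   `w_dist`, `w_risk` and `label`.
#' @examples
#' objective_spec("R")                       # risk only: weights (0, 0, 1)
#' objective_spec(weights = c(1, 0.25, 2))   # custom trade-off
#' @export
objective_spec <- function(label = NULL, weights = NULL) {
  if (!is.null(label) && !is.null(weights)) {
    canon <- toupper(label)
    if (canon != "CUSTOM") {
      stop_usage("give either a named objective label or explicit weights, not both")
    }
    label <- NULL
  }
  if (is.null(label) && is.null(weights)) {
    stop_usage("one of `label` or `weights` is required")
  }
  if (!is.null(label)) {
    canon <- SWEEP_LABELS[match(toupper(label), toupper(SWEEP_LABELS))]
    if (is.na(canon)) {
      stop_usage("unknown objective label '%s'; choose one of %s",
                 label, paste(SWEEP_LABELS, collapse = ", "))
    }
    w <- label_weights(canon)
    label <- canon
  } else {
    weights <- unlist(weights)
    if (length(weights) != 3L || !all(vapply(as.list(weights), is_number, TRUE))) {
      stop_usage("`weights` must be three finite numbers (w_rtt, w_dist, w_risk)")
    }
    if (!is.null(names(weights)) && all(c("w_rtt", "w_dist", "w_risk") %in% names(weights))) {
      weights <- weights[c("w_rtt", "w_dist", "w_risk")]
    }
    w <- c(w_rtt = as.numeric(weights[[1L]]),
           w_dist = as.numeric(weights[[2L]]),
           w_risk = as.numeric(weights[[3L]]))
    if (any(w < 0)) stop_usage("objective weights must be non-negative")
    if (all(w == 0)) stop_usage("at least one objective weight must be strictly positive")
    hit <- vapply(SWEEP_LABELS, function(l) isTRUE(all.equal(unname(label_weights(l)), unname(w))), TRUE)
    label <- if (any(hit)) SWEEP_LABELS[which(hit)[1L]] else "custom"
  }
  structure(list(w_rtt = w[["w_rtt"]], w_dist = w[["w_dist"]],
                 w_risk = w[["w_risk"]], label = label),
            class = "objective_spec")
}

#' @export
print.objective_spec <- function(x, ...) {
  cat(sprintf("Objective '%s': maximize %s*RTT + %s*distance + %s*risk\n",
              x$label, x$w_rtt, x$w_dist, x$w_risk))
  invisible(x)
}

#' Per-(patient, clinic) objective coefficients
#'
#' Assembles the coefficient of each binary assignment variable: scheduling
#' patient p at clinic l (on any day) contributes
#' `w_rtt * RTT_p + w_risk * R(risk_p) + w_dist * D_{p,l}` to the
#' objective.  The coefficient never depends on the day of the appointment,
#' so it is returned as a patient-by-clinic matrix that applies uniformly to
#' every day of the horizon; it depends on the clinic only through the
#' distance term (so all columns are equal when `w_dist = 0`).
#'
#' @param instance a valid [sched_instance()].
#' @param objective an [objective_spec()].
#' @return Numeric `P x L` matrix, row names patient ids, column names
#'   clinic ids.
#' @examples
#' inst <- case_study_instance(seed = 1)
#' cf <- build_coefficients(inst, objective_spec("RTT+D+R"))
#' dim(cf)
#' @export
build_coefficients <- function(instance, objective) {
  stop_if_invalid(instance)
  stopifnot(inherits(objective, "objective_spec"))
  p <- instance$patients
  D <- distance_matrix(instance)
  base <- objective$w_rtt * p$rtt_weeks +
    objective$w_risk * as.numeric(instance$risk_weights[p$risk_category])
  cf <- matrix(base, nrow = nrow(p), ncol = ncol(D)) + objective$w_dist * D
  dimnames(cf) <- dimnames(D)
  cf
}
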