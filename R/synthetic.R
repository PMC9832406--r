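# Seeded generators for cohorts and capacity calendars emulating the study
# conditions: 519 patients on the waiting list, 329 slots across 3 clinics
# over a 6-week horizon, distance scores uniform on [1, 50], risk weights
# 1000/10/1.

#' Cohort generator specification
#'
#' @param n_patients number of patients to generate.
#' @param risk_composition named vector over `R1`, `R2`, `R3`: exact counts
#'   (summing to `n_patients`) or category probabilities (summing to 1).
#'   Default: the case-study composition scaled to `n_patients`
#'   proportions via probabilities (235/519, 256/519, 28/519).
#' @param rtt_range inclusive integer bounds for the uniformly drawn RTT
#'   (weeks since referral).  Default 1--104 weeks (up to a two-year
#'   backlog): with the default risk weighting, the R1 score of 1000 then
#'   dominates any combined RTT + distance contribution (at most
#'   104 + 50 = 154), preserving risk-first prioritization.
#' @param distance_bounds inclusive bounds of the uniform distance score,
#'   default `c(1, 50)`; lower bound must be >= 1.
#' @param locations clinic ids the cohort will carry distance scores for.
#' @param distance_integer draw integer scores (default; the 1--50 score
#'   framing is discrete) or continuous uniforms.
#' @param seed integer seed making the draw reproducible.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_patients,
                        risk_composition = c(R1 = 235 / 519, R2 = 256 / 519, R3 = 28 / 519),
                        rtt_range = c(1L, 104L),
                        distance_bounds = c(1, 50),
                        locations = c("A", "B", "C"),
                        distance_integer = TRUE,
                        seed = 1L) {
  if (!is_count(n_patients)) stop_validation("n_patients must be a non-negative count")
  rc <- risk_composition
  if (is.null(names(rc)) || !setequal(names(rc), RISK_CATEGORIES)) {
    stop_validation("risk_composition must be named over %s",
                    paste(RISK_CATEGORIES, collapse = ", "))
  }
  rc <- rc[RISK_CATEGORIES]
  if (any(rc < 0)) stop_validation("risk_composition entries must be non-negative")
  as_counts <- all(rc == round(rc)) && sum(rc) > 1.5
  if (as_counts && sum(rc) != n_patients) {
    stop_validation("risk composition counts sum to %d, not n_patients = %d",
                    sum(rc), n_patients)
  }
  if (!as_counts && abs(sum(rc) - 1) > 1e-8 && n_patients > 0) {
    stop_validation("risk composition probabilities must sum to 1")
  }
  if (length(rtt_range) != 2L || rtt_range[1L] < 0 || rtt_range[2L] < rtt_range[1L]) {
    stop_validation("rtt_range must be non-negative bounds (low, high)")
  }
  if (length(distance_bounds) != 2L || distance_bounds[1L] < 1 ||
      distance_bounds[2L] < distance_bounds[1L]) {
    stop_validation("distance_bounds must satisfy 1 <= low <= high")
  }
  structure(list(n_patients = as.integer(n_patients),
                 risk_composition = rc, as_counts = as_counts,
                 rtt_range = as.integer(rtt_range),
                 distance_bounds = distance_bounds,
                 locations = as.character(locations),
                 distance_integer = isTRUE(distance_integer),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Deterministic given the spec's seed: same seed, byte-identical cohort.
#' RTT values are uniform integers on `rtt_range`; each patient draws one
#' distance score per clinic, uniform on `distance_bounds` (integers by
#' default); risk categories follow the composition exactly when given as
#' counts (shuffled across patients), or are sampled when given as
#' probabilities.
#'
#' @param spec a [cohort_spec()].
#' @return A patients data frame suitable for [sched_instance()]:
#'   `patient_id`, `rtt_weeks`, `risk_category`, one `dist_<clinic>` column
#'   per location.
#' @examples
#' head(generate_cohort(cohort_spec(10, seed = 7)))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  if (n == 0L) {
    out <- data.frame(patient_id = character(), rtt_weeks = numeric(),
                      risk_category = character(), stringsAsFactors = FALSE)
    for (loc in spec$locations) out[[paste0("dist_", loc)]] <- numeric()
    return(out)
  }
  with_seed(spec$seed, {
    risk <- if (spec$as_counts) {
      sample(rep(RISK_CATEGORIES, times = spec$risk_composition))
    } else {
      sample(RISK_CATEGORIES, n, replace = TRUE, prob = spec$risk_composition)
    }
    rtt <- sample(seq(spec$rtt_range[1L], spec$rtt_range[2L]), n, replace = TRUE)
    out <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                      rtt_weeks = as.numeric(rtt),
                      risk_category = risk,
                      stringsAsFactors = FALSE)
    lo <- spec$distance_bounds[1L]
    hi <- spec$distance_bounds[2L]
    for (loc in spec$locations) {
      out[[paste0("dist_", loc)]] <- if (spec$distance_integer) {
        as.numeric(sample(seq(lo, hi), n, replace = TRUE))
      } else {
        runif(n, lo, hi)
      }
    }
    out
  })
}

#' Capacity calendar specification
#'
#' @param n_clinics number of clinics (locations named "A", "B", ... unless
#'   `locations` is given).
#' @param horizon_weeks planning-horizon length in weeks.
#' @param days_per_week clinic days per week (default 5, a working week);
#'   the horizon spans `horizon_weeks * days_per_week` days.
#' @param total_capacity total number of bookable slots over the horizon.
#' @param split_policy `"even_round_robin"` spreads the total as evenly as
#'   possible over all clinic-day cells, handing the remainder out one slot
#'   at a time in day-then-clinic order (cell capacities differ by at most
#'   one); `"explicit"` uses `explicit_capacity` verbatim.
#' @param explicit_capacity an `n_clinics x horizon-days` matrix summing to
#'   `total_capacity` (only with `split_policy = "explicit"`).
#' @param locations optional clinic ids.
#' @return A list of class `"calendar_spec"`.
#' @export
calendar_spec <- function(n_clinics = 3L, horizon_weeks = 6L,
                          days_per_week = 5L, total_capacity = 329L,
                          split_policy = c("even_round_robin", "explicit"),
                          explicit_capacity = NULL, locations = NULL) {
  split_policy <- match.arg(split_policy)
  if (!is_count(n_clinics) || n_clinics < 1) stop_validation("n_clinics must be >= 1")
  if (!is_count(horizon_weeks) || horizon_weeks < 1) stop_validation("horizon_weeks must be >= 1")
  if (!is_count(days_per_week) || days_per_week < 1) stop_validation("days_per_week must be >= 1")
  if (!is_count(total_capacity)) stop_validation("total_capacity must be a non-negative count")
  if (is.null(locations)) locations <- LETTERS[seq_len(n_clinics)]
  if (length(locations) != n_clinics) stop_validation("need %d location ids", n_clinics)
  structure(list(n_clinics = as.integer(n_clinics),
                 horizon_weeks = as.integer(horizon_weeks),
                 days_per_week = as.integer(days_per_week),
                 total_capacity = as.integer(total_capacity),
                 split_policy = split_policy,
                 explicit_capacity = explicit_capacity,
                 locations = as.character(locations)),
            class = "calendar_spec")
}

#' Generate a capacity calendar
#'
#' @param spec a [calendar_spec()].  The generated per-cell capacities sum
#'   exactly to `total_capacity`; with the even round-robin policy the
#'   cell capacities differ by at most one slot.
#' @return A [capacity_calendar()].
#' @examples
#' cal <- generate_calendar(calendar_spec())  # 3 clinics x 30 days, 329 slots
#' total_capacity(cal)
#' @export
generate_calendar <- function(spec) {
  stopifnot(inherits(spec, "calendar_spec"))
  T_ <- spec$horizon_weeks * spec$days_per_week
  L <- spec$n_clinics
  if (spec$split_policy == "explicit") {
    m <- as.matrix(spec$explicit_capacity)
    if (is.null(m) || nrow(m) != L || ncol(m) != T_) {
      stop_validation("explicit_capacity must be a %d x %d matrix", L, T_)
    }
    if (sum(m) != spec$total_capacity) {
      stop_validation("explicit split sums to %d, not total_capacity = %d",
                      sum(m), spec$total_capacity)
    }
    rownames(m) <- spec$locations
    return(capacity_calendar(m))
  }
  cells <- L * T_
  base <- spec$total_capacity %/% cells
  rem <- spec$total_capacity %% cells
  m <- matrix(base, L, T_, dimnames = list(spec$locations, NULL))
  if (rem > 0) {
    # hand out the remainder one slot at a time, day-major then clinic
    idx <- seq_len(rem) - 1L
    m[cbind(idx %% L + 1L, idx %/% L + 1L)] <-
      m[cbind(idx %% L + 1L, idx %/% L + 1L)] + 1L
  }
  capacity_calendar(m)
}

#' The case-study instance
#'
#' A ready-made synthetic instance emulating the published eye-care
#' case study this tool was built around: 519 patients on the waiting list
#' (235 R1, 256 R2, 28 R3 -- the composition is uniquely recoverable from
#' the reported risk totals under the 1000/10/1 weighting: a scheduled risk
#' score of 235,940 over 329 slots forces 235 R1 + 94 R2 scheduled, and a
#' remaining score of 1648 over 190 patients forces 162 R2 + 28 R3
#' unscheduled), 329 slots split evenly across 3 clinics over a 6-week
#' (30 working-day) horizon, RTT uniform on 1--104 weeks and distance
#' scores uniform on 1--50.  The per-patient RTT and distance values are
#' synthetic draws: the real cohort's values were never published, so
#' quantities that depend on them (e.g. the RTT-optimal total) vary with
#' the seed, while saturation counts and the risk optimum do not.
#'
#' @param seed integer seed for the cohort draw (fixed default, so the
#'   fixture is reproducible).
#' @return A [sched_instance()] with the default [risk_weights()].
#' @examples
#' inst <- case_study_instance()
#' table(inst$patients$risk_category)
#' total_capacity(inst$calendar)
#' @export
case_study_instance <- function(seed = 20230111L) {
  cohort <- generate_cohort(cohort_spec(
    n_patients = 519L,
    risk_composition = c(R1 = 235L, R2 = 256L, R3 = 28L),
    rtt_range = c(1L, 104L),
    distance_bounds = c(1, 50),
    locations = c("A", "B", "C"),
    seed = seed))
  calendar <- generate_calendar(calendar_spec(
    n_clinics = 3L, horizon_weeks = 6L, days_per_week = 5L,
    total_capacity = 329L))
  sched_instance(cohort, calendar, risk_weights())
}
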