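# Exact solution of the capacity-constrained assignment problem:
#   maximize sum_{p,l,t} c_{p,l} x_{p,l,t}
#   s.t.     sum_{l,t} x_{p,l,t} <= 1        for every patient p
#            sum_p     x_{p,l,t} <= C_{l,t}  for every clinic l, day t
#            x binary.
# The constraint matrix has transportation structure, so the LP relaxation
# has an integral optimal vertex and network-flow methods are exact.

# Integer scale applied to objective coefficients before flow arithmetic;
# coefficients are exact to 1e-6 (integral study data is exact throughout).
COEF_SCALE <- 1e6
COEF_MAX <- 1e7

#' Solver options
#'
#' @param method `"min_cost_flow"` (default; compiled successive-shortest-
#'   paths on the clinic-aggregated network, scales to thousands of
#'   patients), `"lp_relaxation"` (dense simplex on the literal slot-level
#'   LP via [boot::simplex()], size-guarded, solutions verified integral and
#'   rounded), or `"milp"` (branch-and-bound over the LP relaxation; by
#'   total unimodularity it normally terminates at the root node).
#' @param tie_break how alternative optima are broken deterministically:
#'   `"by_patient_id"` (ascending id, then earliest day, then calendar
#'   clinic order) or `"by_input_order"` (waiting-list row order).
#' @param integrality_tolerance maximum distance from {0, 1} tolerated in an
#'   LP-relaxation solution before rounding; must be < 0.5.
#' @return A list of class `"solver_options"`.
#' @export
solver_options <- function(method = c("min_cost_flow", "lp_relaxation", "milp"),
                           tie_break = c("by_patient_id", "by_input_order"),
                           integrality_tolerance = 1e-6) {
  method <- match.arg(method)
  tie_break <- match.arg(tie_break)
  if (!is_number(integrality_tolerance) ||
      integrality_tolerance <= 0 || integrality_tolerance >= 0.5) {
    stop_validation("integrality_tolerance must lie in (0, 0.5)")
  }
  structure(list(method = method, tie_break = tie_break,
                 integrality_tolerance = integrality_tolerance),
            class = "solver_options")
}

patient_rank <- function(instance, tie_break) {
  if (tie_break == "by_patient_id") {
    order(instance$patients$patient_id)
  } else {
    seq_len(nrow(instance$patients))
  }
}

#' Solve for an optimal schedule
#'
#' Computes a globally optimal assignment of patients to (clinic, day)
#' slots for the given objective.  The returned schedule is always
#' feasible; every patient receives at most one appointment across all
#' clinics and days, and no clinic-day exceeds its capacity.  When all
#' objective coefficients are strictly positive and demand exceeds supply,
#' optimality forces every slot to be filled, so exactly
#' `min(n_patients, total_capacity)` patients are scheduled.
#'
#' An empty schedule is always feasible, so the solve cannot be
#' infeasible; an internal solver failure raises an error carrying
#' diagnostics.
#'
#' @param instance a [sched_instance()] that passes [validate_instance()].
#' @param objective an [objective_spec()].
#' @param options a [solver_options()].
#' @return An object of class `"sched_schedule"`: list with `assignments`
#'   (data frame `patient_id`, `clinic`, `day`), `objective_value`,
#'   `unscheduled` (patient ids), `objective`, `method`.
#' @examples
#' inst <- case_study_instance(seed = 1)
#' sch <- solve_schedule(inst, objective_spec("R"))
#' sch$objective_value        # 235940 under the default risk weighting
#' nrow(sch$assignments)      # 329: every slot filled
#' @export
solve_schedule <- function(instance, objective,
                           options = solver_options()) {
  stop_if_invalid(instance)
  stopifnot(inherits(objective, "objective_spec"),
            inherits(options, "solver_options"))
  coeff <- build_coefficients(instance, objective)
  if (nrow(coeff) && max(abs(coeff)) > COEF_MAX) {
    stop_validation("objective coefficients exceed %g; rescale the weights",
                    COEF_MAX)
  }
  sol <- switch(options$method,
                min_cost_flow = solve_mcf(instance, coeff, options),
                lp_relaxation = solve_lp(instance, coeff, options),
                milp = solve_milp(instance, coeff, options))
  assignments <- sol$assignments
  rownames(assignments) <- NULL
  value <- if (nrow(assignments)) {
    sum(coeff[cbind(match(assignments$patient_id, rownames(coeff)),
                    match(assignments$clinic, colnames(coeff)))])
  } else 0
  structure(list(assignments = assignments,
                 objective_value = value,
                 unscheduled = setdiff(instance$patients$patient_id,
                                       assignments$patient_id),
                 objective = objective,
                 method = options$method),
            class = "sched_schedule")
}

#' @export
print.sched_schedule <- function(x, ...) {
  cat(sprintf("Schedule (objective '%s', method %s): %d scheduled, %d unscheduled, objective value %s\n",
              x$objective$label, x$method, nrow(x$assignments),
              length(x$unscheduled), format(x$objective_value, big.mark = ",")))
  invisible(x)
}

#' @export
summary.sched_schedule <- function(object, ...) {
  print(object)
  if (nrow(object$assignments)) {
    cat("Assignments per clinic:\n")
    print(table(object$assignments$clinic))
    cat("Day range used:", min(object$assignments$day), "-",
        max(object$assignments$day), "\n")
  }
  invisible(object)
}

# --- min-cost-flow method ---------------------------------------------------
# Coefficients are day-independent, so patients are assigned to *clinics*
# through a flow network (aggregated clinic capacities); day slots are then
# filled deterministically in tie-break order, earliest day first.
solve_mcf <- function(instance, coeff, options) {
  P <- nrow(coeff)
  locs <- instance$calendar$locations
  L <- length(locs)
  if (P == 0L) {
    return(list(assignments = empty_assignments()))
  }
  rk <- patient_rank(instance, options$tie_break)  # row indices in rank order
  ci <- round(coeff * COEF_SCALE)
  loc_cap <- rowSums(instance$calendar$capacity)

  src <- 1L
  pat_node <- 1L + seq_len(P)            # in rank order
  loc_node <- 1L + P + seq_len(L)
  ovf <- 1L + P + L + 1L
  snk <- ovf + 1L

  from <- c(rep(src, P),
            rep(pat_node, each = L),
            pat_node,
            loc_node,
            ovf)
  to <- c(pat_node,
          rep(loc_node, times = P),
          rep(ovf, P),
          rep(snk, L),
          snk)
  cap <- c(rep(1L, P),
           rep(1L, P * L),
           rep(1L, P),
           as.integer(loc_cap),
           P)
  cost <- c(rep(0, P),
            -as.numeric(t(ci[rk, , drop = FALSE])),  # profit -> negated cost
            rep(0, P),
            rep(0, L),
            0)
  res <- mcf_run(snk, from, to, cap, cost, src, snk, P)
  if (res$flow_value != P) {
    stop(errorCondition(
      sprintf("flow solver failed to route all patients (%d of %d); arcs=%d",
              res$flow_value, P, length(from)),
      class = c("clinicsched_solver_error", "error")))
  }
  af <- res$flow[P + seq_len(P * L)]  # flows on patient->clinic arcs
  sel <- which(af == 1L)
  rank_idx <- (sel - 1L) %/% L + 1L      # position in rank order
  loc_idx <- (sel - 1L) %% L + 1L
  expand_days(instance, options,
              patient_row = rk[rank_idx], loc_idx = loc_idx,
              rank_pos = rank_idx)
}

empty_assignments <- function() {
  data.frame(patient_id = character(), clinic = character(),
             day = integer(), stringsAsFactors = FALSE)
}

# Assign concrete days: within each clinic, patients in tie-break order get
# the earliest day cells with remaining capacity.
expand_days <- function(instance, options, patient_row, loc_idx, rank_pos) {
  if (!length(patient_row)) return(list(assignments = empty_assignments()))
  capmat <- instance$calendar$capacity
  locs <- instance$calendar$locations
  out <- vector("list", length(locs))
  for (j in seq_along(locs)) {
    here <- which(loc_idx == j)
    here <- here[order(rank_pos[here])]
    if (!length(here)) next
    days <- rep(seq_len(ncol(capmat)), times = capmat[j, ])
    if (length(here) > length(days)) {
      stop(errorCondition(
        sprintf("internal error: %d patients routed to clinic '%s' with %d slots",
                length(here), locs[j], length(days)),
        class = c("clinicsched_solver_error", "error")))
    }
    out[[j]] <- data.frame(
      patient_id = instance$patients$patient_id[patient_row[here]],
      clinic = locs[j],
      day = days[seq_along(here)],
      stringsAsFactors = FALSE)
  }
  list(assignments = do.call(rbind, c(out, list(empty_assignments()))))
}

# --- LP relaxation method ---------------------------------------------------
# The literal slot-level formulation, solved with a dense two-phase simplex.
# Dense pure-R pivoting limits this route to modest instances; it exists to
# cross-validate the flow method against the model exactly as written.
LP_MAX_VARS <- 6000L

lp_variables <- function(instance) {
  P <- nrow(instance$patients)
  locs <- instance$calendar$locations
  T_ <- instance$calendar$horizon_days
  cells <- which(instance$calendar$capacity > 0, arr.ind = TRUE)  # l, t
  list(P = P, L = length(locs), T_ = T_, cells = cells,
       n_var = P * nrow(cells))
}

solve_lp_core <- function(instance, coeff, vars, fix0 = integer(), fix1 = integer()) {
  P <- vars$P
  ncell <- nrow(vars$cells)
  n <- vars$n_var
  # variable index: (p, cell) with cell varying fastest
  obj <- as.numeric(t(coeff[, vars$cells[, 1L], drop = FALSE]))
  # patient rows
  A_pat <- matrix(0, P, n)
  for (p in seq_len(P)) A_pat[p, (p - 1L) * ncell + seq_len(ncell)] <- 1
  # cell rows
  A_cell <- matrix(0, ncell, n)
  for (k in seq_len(ncell)) A_cell[k, seq(k, n, by = ncell)] <- 1
  b_cell <- instance$calendar$capacity[vars$cells]
  A1 <- rbind(A_pat, A_cell)
  b1 <- c(rep(1, P), b_cell)
  if (length(fix0)) {
    Af <- matrix(0, length(fix0), n)
    Af[cbind(seq_along(fix0), fix0)] <- 1
    A1 <- rbind(A1, Af)
    b1 <- c(b1, rep(0, length(fix0)))
  }
  A2 <- NULL; b2 <- NULL
  if (length(fix1)) {
    A2 <- matrix(0, length(fix1), n)
    A2[cbind(seq_along(fix1), fix1)] <- 1
    b2 <- rep(1, length(fix1))
  }
  boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                maxi = TRUE, eps = 1e-9)
}

lp_to_assignments <- function(instance, vars, x, tol, options) {
  near0 <- abs(x) <= tol
  near1 <- abs(x - 1) <= tol
  if (!all(near0 | near1)) {
    frac <- which(!(near0 | near1))
    stop(errorCondition(
      sprintf("LP relaxation returned %d non-integral value(s) beyond tolerance %g (max deviation %.3g); transportation integrality violated?",
              length(frac), tol, max(pmin(abs(x[frac]), abs(x[frac] - 1)))),
      class = c("clinicsched_solver_error", "error")))
  }
  sel <- which(near1)
  ncell <- nrow(vars$cells)
  p_idx <- (sel - 1L) %/% ncell + 1L
  cell <- (sel - 1L) %% ncell + 1L
  list(assignments = data.frame(
    patient_id = instance$patients$patient_id[p_idx],
    clinic = instance$calendar$locations[vars$cells[cell, 1L]],
    day = as.integer(vars$cells[cell, 2L]),
    stringsAsFactors = FALSE))
}

solve_lp <- function(instance, coeff, options) {
  vars <- lp_variables(instance)
  if (vars$n_var == 0L) return(list(assignments = empty_assignments()))
  if (vars$n_var > LP_MAX_VARS) {
    stop_validation(
      "lp_relaxation is limited to %d slot-level variables (instance has %d); use method = 'min_cost_flow'",
      LP_MAX_VARS, vars$n_var)
  }
  fit <- solve_lp_core(instance, coeff, vars)
  if (fit$solved != 1) {
    stop(errorCondition(
      sprintf("simplex did not converge (status %d)", fit$solved),
      class = c("clinicsched_solver_error", "error")))
  }
  lp_to_assignments(instance, vars, fit$soln, options$integrality_tolerance,
                    options)
}

# --- branch and bound over the LP relaxation --------------------------------
solve_milp <- function(instance, coeff, options) {
  vars <- lp_variables(instance)
  if (vars$n_var == 0L) return(list(assignments = empty_assignments()))
  if (vars$n_var > LP_MAX_VARS) {
    stop_validation(
      "milp is limited to %d slot-level variables (instance has %d); use method = 'min_cost_flow'",
      LP_MAX_VARS, vars$n_var)
  }
  tol <- options$integrality_tolerance
  best <- list(value = -Inf, x = NULL)
  recurse <- function(fix0, fix1) {
    fit <- solve_lp_core(instance, coeff, vars, fix0, fix1)
    if (fit$solved == -1) return(invisible(NULL))       # infeasible branch
    if (fit$solved != 1) {
      stop(errorCondition(sprintf("simplex did not converge (status %d)", fit$solved),
                          class = c("clinicsched_solver_error", "error")))
    }
    if (fit$value <= best$value + 1e-9) return(invisible(NULL))  # bound
    x <- fit$soln
    frac <- which(pmin(abs(x), abs(x - 1)) > tol)
    if (!length(frac)) {
      best <<- list(value = fit$value, x = x)
      return(invisible(NULL))
    }
    j <- frac[which.max(pmin(abs(x[frac]), abs(x[frac] - 1)))]
    recurse(fix0, c(fix1, j))
    recurse(c(fix0, j), fix1)
    invisible(NULL)
  }
  recurse(integer(), integer())
  if (is.null(best$x)) {
    stop(errorCondition("branch and bound found no feasible leaf",
                        class = c("clinicsched_solver_error", "error")))
  }
  lp_to_assignments(instance, vars, best$x, tol, options)
}

# --- feasibility ------------------------------------------------------------

#' Check a schedule against the model constraints
#'
#' Verifies the three constraints of the assignment model on any schedule
#' (solver output or hand-built): (1) each patient holds at most one
#' appointment across all clinics and days; (2) no clinic-day cell exceeds
#' its capacity; (3) every assignment references a known patient, a known
#' clinic and a day within the horizon.  Violations are returned as text,
#' never thrown.
#'
#' @param instance a [sched_instance()].
#' @param schedule a `"sched_schedule"` or any list with an `assignments`
#'   data frame (`patient_id`, `clinic`, `day`).
#' @return Character vector of violations; empty if the schedule is feasible.
#' @export
check_feasibility <- function(instance, schedule) {
  a <- schedule$assignments
  v <- character()
  if (is.null(a)) return("schedule has no assignments table")
  if (!nrow(a)) return(v)
  known <- instance$patients$patient_id
  locs <- instance$calendar$locations
  T_ <- instance$calendar$horizon_days
  for (id in unique(a$patient_id[!(a$patient_id %in% known)])) {
    v <- c(v, sprintf("assignment references unknown patient '%s'", id))
  }
  for (id in unique(a$patient_id[duplicated(a$patient_id)])) {
    v <- c(v, sprintf("patient '%s' is scheduled more than once", id))
  }
  for (cl in unique(a$clinic[!(a$clinic %in% locs)])) {
    v <- c(v, sprintf("assignment references unknown clinic '%s'", cl))
  }
  bad_day <- a$day != round(a$day) | a$day < 1 | a$day > T_
  for (i in which(bad_day)) {
    v <- c(v, sprintf("patient '%s': day %s outside horizon 1..%d",
                      a$patient_id[i], a$day[i], T_))
  }
  ok <- a$clinic %in% locs & !bad_day
  if (any(ok)) {
    counts <- table(a$clinic[ok], a$day[ok])
    for (cl in rownames(counts)) for (d in colnames(counts)) {
      used <- counts[cl, d]
      lim <- instance$calendar$capacity[match(cl, locs), as.integer(d)]
      if (used > lim) {
        v <- c(v, sprintf("capacity exceeded at clinic '%s', day %s: %d booked, %d slots",
                          cl, d, used, lim))
      }
    }
  }
  v
}

#' Build a schedule object from explicit assignments
#'
#' Convenience constructor for hand-built or externally produced schedules
#' (the objective value is computed from the instance when an objective is
#' given).  No feasibility checking is performed here; use
#' [check_feasibility()].
#'
#' @param instance a [sched_instance()].
#' @param assignments data frame with columns `patient_id`, `clinic`, `day`.
#' @param objective optional [objective_spec()] used to value the schedule.
#' @return A `"sched_schedule"` object.
#' @export
as_schedule <- function(instance, assignments, objective = NULL) {
  assignments <- as.data.frame(assignments, stringsAsFactors = FALSE)
  assignments$patient_id <- as.character(assignments$patient_id)
  assignments$clinic <- as.character(assignments$clinic)
  assignments$day <- as.integer(assignments$day)
  value <- NA_real_
  if (!is.null(objective) && !length(check_feasibility(instance, list(assignments = assignments)))) {
    coeff <- build_coefficients(instance, objective)
    value <- if (nrow(assignments)) {
      sum(coeff[cbind(match(assignments$patient_id, rownames(coeff)),
                      match(assignments$clinic, colnames(coeff)))])
    } else 0
  }
  structure(list(assignments = assignments,
                 objective_value = value,
                 unscheduled = setdiff(instance$patients$patient_id,
                                       assignments$patient_id),
                 objective = objective,
                 method = "manual"),
            class = "sched_schedule")
}
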