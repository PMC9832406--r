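# Independent exact computations of the optimal objective value, used to
# verify the solver.  Each oracle takes a deliberately different route:
# greedy top-K selection (valid only when coefficients are clinic-
# independent), a pure-R Bellman-Ford successive-shortest-paths flow on the
# slot-level bipartite network, and exhaustive enumeration on micro
# instances.

#' Greedy top-K oracle
#'
#' When the distance weight is zero, a patient's coefficient is identical
#' at every clinic and day, so *any* set of K = min(P, total capacity)
#' patients can be packed into the K slots and the optimum is simply the
#' sum of the K largest per-patient coefficients.
#'
#' @param instance a valid [sched_instance()].
#' @param objective an [objective_spec()] with `w_dist == 0`.
#' @return The optimal objective value (a number).
#' @examples
#' inst <- case_study_instance(seed = 1)
#' greedy_oracle(inst, objective_spec("R"))   # 235940
#' @export
greedy_oracle <- function(instance, objective) {
  stop_if_invalid(instance)
  stopifnot(inherits(objective, "objective_spec"))
  if (objective$w_dist != 0) {
    stop_validation("greedy_oracle requires w_dist = 0 (coefficients must be clinic-independent)")
  }
  p <- instance$patients
  cf <- objective$w_rtt * p$rtt_weeks +
    objective$w_risk * as.numeric(instance$risk_weights[p$risk_category])
  K <- min(nrow(p), total_capacity(instance$calendar))
  if (K == 0L) return(0)
  sum(sort(cf, decreasing = TRUE)[seq_len(K)])
}

#' Network-flow oracle
#'
#' Computes the optimum as a maximum-profit flow on the slot-level
#' bipartite network: source -> one node per patient -> one node per
#' (clinic, day) slot cell (capacity C_{l,t}) -> sink, with a zero-profit
#' overflow node absorbing unscheduled patients.  Implemented in pure R as
#' Bellman-Ford successive shortest paths on integer-scaled costs -- a
#' different algorithm, granularity and language from the compiled solver,
#' so agreement between the two is a genuine dual-route check.
#'
#' Intended for verification at small-to-moderate size (hundreds of
#' patients); the solver itself is the fast path.
#'
#' @inheritParams greedy_oracle
#' @param objective an [objective_spec()].
#' @return The optimal objective value.
#' @export
flow_oracle <- function(instance, objective) {
  stop_if_invalid(instance)
  coeff <- build_coefficients(instance, objective)
  P <- nrow(coeff)
  if (P == 0L) return(0)
  cells <- which(instance$calendar$capacity > 0, arr.ind = TRUE)  # (l, t)
  S <- nrow(cells)
  ci <- round(coeff * COEF_SCALE)

  # nodes: 1 = source, 1+1..1+P patients, 1+P+1..1+P+S slot cells,
  # overflow, sink
  src <- 1L
  pat <- 1L + seq_len(P)
  slot <- 1L + P + seq_len(S)
  ovf <- 2L + P + S
  snk <- 3L + P + S
  n_nodes <- snk

  from <- c(rep(src, P),
            if (S) rep(pat, each = S),
            pat,
            if (S) slot,
            ovf)
  to <- c(pat,
          if (S) rep(slot, times = P),
          rep(ovf, P),
          if (S) rep(snk, S),
          snk)
  capa <- c(rep(1L, P),
            if (S) rep(1L, P * S),
            rep(1L, P),
            if (S) as.integer(instance$calendar$capacity[cells]),
            P)
  cost <- c(rep(0, P),
            if (S) as.numeric(t(ci[, cells[, 1L], drop = FALSE])) * -1,
            rep(0, P),
            if (S) rep(0, S),
            0)

  # paired residual arcs: forward arc 2i-1, reverse arc 2i
  A <- length(from)
  efrom <- integer(2L * A); eto <- integer(2L * A)
  ecost <- numeric(2L * A); ecap <- integer(2L * A)
  fidx <- 2L * seq_len(A) - 1L
  efrom[fidx] <- from;  eto[fidx] <- to
  ecost[fidx] <- cost;  ecap[fidx] <- capa
  efrom[fidx + 1L] <- to;  eto[fidx + 1L] <- from
  ecost[fidx + 1L] <- -cost  # reverse capacity starts at 0
  partner <- ifelse(seq_len(2L * A) %% 2L == 1L,
                    seq_len(2L * A) + 1L, seq_len(2L * A) - 1L)
  in_arcs <- split(seq_len(2L * A), eto)

  node_ids <- as.integer(names(in_arcs))
  for (unit in seq_len(P)) {
    # Bellman-Ford from the source over the residual graph.  Parents are
    # recorded only on strict improvement, which keeps the predecessor
    # graph acyclic even in the presence of zero-cost residual cycles.
    d <- rep(Inf, n_nodes); d[src] <- 0
    par <- integer(n_nodes)
    for (pass in seq_len(n_nodes + 1L)) {
      cand <- d[efrom] + ecost
      cand[ecap == 0L] <- Inf
      changed <- FALSE
      for (k in seq_along(node_ids)) {
        ix <- in_arcs[[k]]
        j <- which.min(cand[ix])
        vi <- node_ids[k]
        if (cand[ix[j]] < d[vi]) {
          d[vi] <- cand[ix[j]]
          par[vi] <- ix[j]
          changed <- TRUE
        }
      }
      if (!changed) break
      if (pass > n_nodes) stop("flow oracle: relaxation failed to converge")
    }
    if (!is.finite(d[snk])) break  # cannot happen: overflow path always open
    v <- snk
    steps <- 0L
    while (v != src) {
      e <- par[v]
      ecap[e] <- ecap[e] - 1L
      ecap[partner[e]] <- ecap[partner[e]] + 1L
      v <- efrom[e]
      steps <- steps + 1L
      if (steps > 2L * n_nodes) stop("flow oracle: cyclic predecessor chain")
    }
  }

  if (S == 0L) return(0)
  pl_arcs <- fidx[P + seq_len(P * S)]          # forward patient->slot arcs
  used <- which(ecap[pl_arcs] == 0L)           # unit flow consumed the arc
  if (!length(used)) return(0)
  p_idx <- (used - 1L) %/% S + 1L
  cell <- (used - 1L) %% S + 1L
  sum(coeff[cbind(p_idx, cells[cell, 1L])])
}

#' Brute-force oracle
#'
#' Exact optimum by exhaustive enumeration of every feasible assignment,
#' including leaving patients unscheduled.  Because objective coefficients
#' never depend on the day, choices at the same clinic are interchangeable
#' and the enumeration runs over per-clinic aggregate capacities; it is
#' still exhaustive over all achievable objective values.  Guarded to at
#' most 8 patients and 8 total slots.
#'
#' @inheritParams flow_oracle
#' @return The optimal objective value.
#' @export
brute_force_oracle <- function(instance, objective) {
  stop_if_invalid(instance)
  P <- nrow(instance$patients)
  tot <- total_capacity(instance$calendar)
  if (P > 8L || tot > 8L) {
    stop_validation("brute_force_oracle guard: at most 8 patients and 8 slots (got %d patients, %d slots)",
                    P, tot)
  }
  if (P == 0L) return(0)
  coeff <- build_coefficients(instance, objective)
  L <- ncol(coeff)
  rem <- rowSums(instance$calendar$capacity)
  best <- -Inf
  recurse <- function(p, acc) {
    if (p > P) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    recurse(p + 1L, acc)                       # leave patient p unscheduled
    for (l in seq_len(L)) {
      if (rem[l] > 0L) {
        rem[l] <<- rem[l] - 1L
        recurse(p + 1L, acc + coeff[p, l])
        rem[l] <<- rem[l] + 1L
      }
    }
    invisible(NULL)
  }
  recurse(1L, 0)
  best
}
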