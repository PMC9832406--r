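# Builders used across the suite.  Everything is generated in code; no
# stored fixtures.

# A small hand-specifiable instance: `dist` is a P x L matrix (or NULL for
# all-ones), `cap` an L x T matrix of slot capacities.
tiny_instance <- function(rtt, risk, cap, dist = NULL,
                          weights = risk_weights()) {
  P <- length(rtt)
  locs <- LETTERS[seq_len(nrow(cap))]
  if (is.null(dist)) dist <- matrix(1, P, length(locs))
  patients <- data.frame(patient_id = sprintf("p%02d", seq_len(P)),
                         rtt_weeks = rtt,
                         risk_category = risk,
                         stringsAsFactors = FALSE)
  for (j in seq_along(locs)) patients[[paste0("dist_", locs[j])]] <- dist[, j]
  rownames(cap) <- locs
  sched_instance(patients, capacity_calendar(cap), weights)
}

# Seeded random instance drawn from the generator module.
rand_instance <- function(P, L = 3, days = 10, totcap = NULL, seed = 1) {
  if (is.null(totcap)) totcap <- max(1L, P %/% 2L)
  cohort <- generate_cohort(cohort_spec(
    P, risk_composition = c(R1 = 0.3, R2 = 0.5, R3 = 0.2),
    locations = LETTERS[seq_len(L)], seed = seed))
  cal <- generate_calendar(calendar_spec(
    n_clinics = L, horizon_weeks = 1L, days_per_week = days,
    total_capacity = totcap))
  sched_instance(cohort, cal)
}

random_label <- function() sample(objective_labels(), 1L)
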