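# Metrics report, conservation identities, the seven-objective sweep.

test_that("conservation identities hold on solver output and on fuzzed subsets", {
  for (s in 1:10) {
    inst <- rand_instance(P = sample(5:25, 1), L = 2, days = 4,
                          totcap = sample(1:15, 1), seed = 600 + s)
    sch <- if (s %% 2 == 0) {
      solve_schedule(inst, objective_spec(random_label()))
    } else {
      # arbitrary feasible sub-schedule: keep a random subset of an optimum
      full <- solve_schedule(inst, objective_spec("RTT+D+R"))
      keep <- sample(nrow(full$assignments),
                     sample(0:nrow(full$assignments), 1))
      as_schedule(inst, full$assignments[keep, , drop = FALSE])
    }
    m <- compute_metrics(inst, sch)
    p <- inst$patients
    risk_score <- as.numeric(inst$risk_weights[p$risk_category])
    expect_equal(m$n_scheduled + m$n_unscheduled, nrow(p))
    expect_equal(m$total_rtt_scheduled + m$remaining_rtt_unscheduled,
                 sum(p$rtt_weeks))
    expect_equal(m$total_risk_scheduled + m$remaining_risk_unscheduled,
                 sum(risk_score))
    if (m$n_scheduled > 0) {
      expect_equal(m$mean_rtt_per_scheduled,
                   m$total_rtt_scheduled / m$n_scheduled)
    }
  }
})

test_that("empty schedule: everything remains on the waiting list", {
  inst <- rand_instance(12, L = 2, days = 3, totcap = 6, seed = 9)
  m <- compute_metrics(inst, as_schedule(inst, data.frame(
    patient_id = character(), clinic = character(), day = integer())))
  expect_equal(m$n_scheduled, 0L)
  expect_equal(m$total_rtt_scheduled, 0)
  expect_equal(m$total_distance_scheduled, 0)
  expect_equal(m$remaining_rtt_unscheduled, sum(inst$patients$rtt_weeks))
  expect_true(is.na(m$mean_rtt_per_scheduled))
})

test_that("infeasible schedules are rejected with the violation list", {
  inst <- tiny_instance(rtt = c(1, 2), risk = c("R1", "R2"),
                        cap = matrix(1, 1, 1))
  bad <- as_schedule(inst, data.frame(patient_id = c("p01", "p02"),
                                      clinic = "A", day = 1))
  expect_error(compute_metrics(inst, bad), "capacity exceeded")
})

test_that("mean RTT presentation rounds to two decimals and keeps the exact value", {
  expect_equal(as.numeric(mean_rtt(8746, 329)), 26.58)
  expect_equal(attr(mean_rtt(8746, 329), "exact"), 8746 / 329)
  expect_equal(as.numeric(mean_rtt(0, 5)), 0)
  expect_equal(as.numeric(mean_rtt(10, 4)), 2.5)
  expect_error(mean_rtt(100, 0), "undefined")
})

test_that("the sweep has the seven canonical rows in order and is internally consistent", {
  inst <- rand_instance(18, L = 3, days = 4, totcap = 10, seed = 77)
  sw <- objective_sweep(inst)
  expect_equal(sw$objective,
               c("RTT", "D", "R", "RTT+D", "D+R", "RTT+R", "RTT+D+R"))
  expect_true(all(sw$n_scheduled + sw$n_unscheduled == nrow(inst$patients)))
  expect_true(all(sw$n_scheduled == min(nrow(inst$patients),
                                        total_capacity(inst$calendar))))
  risk_total <- sum(as.numeric(inst$risk_weights[inst$patients$risk_category]))
  expect_true(all(sw$total_risk_scheduled + sw$remaining_risk_unscheduled ==
                    risk_total))
})

test_that("sweep export carries the report-style column headers", {
  inst <- rand_instance(8, L = 2, days = 2, totcap = 4, seed = 3)
  sw <- objective_sweep(inst)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep(sw, path)
  hdr <- names(read.csv(path, check.names = FALSE))
  expect_equal(hdr[1:2],
               c("Objective",
                 "Total number of weeks from referral to treatment (RTT objective)"))
  expect_length(hdr, 8L)
  expect_match(hdr[6], "remaining RTT for patients that were not scheduled")
  back <- read.csv(path, check.names = FALSE)
  expect_equal(back[["Number of patients scheduled"]], sw$n_scheduled)
})
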