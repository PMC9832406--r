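# Exact solution of the assignment model and feasibility checking.

test_that("single patient, single slot: scheduled at its coefficient value", {
  inst <- tiny_instance(rtt = 4, risk = "R3", cap = matrix(1, 1, 1))
  sch <- solve_schedule(inst, objective_spec("RTT"))
  expect_equal(nrow(sch$assignments), 1L)
  expect_equal(sch$objective_value, 4)
  expect_identical(check_feasibility(inst, sch), character(0))
})

test_that("risk objective picks the two highest-risk of three patients for two slots", {
  inst <- tiny_instance(rtt = c(1, 1, 1), risk = c("R1", "R2", "R3"),
                        cap = matrix(c(1, 1), 1, 2))
  sch <- solve_schedule(inst, objective_spec("R"))
  expect_equal(sch$objective_value, 1010)
  expect_setequal(sch$assignments$patient_id, c("p01", "p02"))
  expect_equal(sch$objective_value, brute_force_oracle(inst, objective_spec("R")))
})

test_that("all methods return the same optimum on small instances", {
  for (s in 1:8) {
    inst <- rand_instance(P = 5 + s, L = 2, days = 3, totcap = 4, seed = s)
    obj <- objective_spec(objective_labels()[(s %% 7) + 1])
    v_flow <- solve_schedule(inst, obj)$objective_value
    v_lp <- solve_schedule(inst, obj, solver_options(method = "lp_relaxation"))
    v_bb <- solve_schedule(inst, obj, solver_options(method = "milp"))
    expect_equal(v_lp$objective_value, v_flow, info = paste("seed", s))
    expect_equal(v_bb$objective_value, v_flow, info = paste("seed", s))
    # LP route asserts integrality internally; its schedule must be feasible
    expect_identical(check_feasibility(inst, v_lp), character(0))
  }
})

test_that("capacity saturation: strictly positive coefficients fill min(P, capacity)", {
  for (s in 1:6) {
    P <- sample(3:20, 1)
    tot <- sample(1:25, 1)
    inst <- rand_instance(P, L = 2, days = 4, totcap = tot, seed = 100 + s)
    sch <- solve_schedule(inst, objective_spec(random_label()))
    expect_equal(nrow(sch$assignments), min(P, tot))
  }
})

test_that("optimum is monotone in capacity and in cohort size", {
  set.seed(42)
  for (s in 1:5) {
    inst <- rand_instance(12, L = 2, days = 3, totcap = 5, seed = 200 + s)
    obj <- objective_spec(random_label())
    v0 <- solve_schedule(inst, obj)$objective_value

    # one extra slot anywhere
    bigger <- inst
    cell <- c(sample(2, 1), sample(3, 1))
    bigger$calendar$capacity[cell[1], cell[2]] <-
      bigger$calendar$capacity[cell[1], cell[2]] + 1L
    expect_gte(solve_schedule(bigger, obj)$objective_value, v0)

    # one extra patient
    extra <- inst
    newp <- extra$patients[1, ]
    newp$patient_id <- "zz_new"
    extra$patients <- rbind(extra$patients, newp)
    expect_gte(solve_schedule(extra, obj)$objective_value, v0)
  }
})

test_that("solves are deterministic and respect the tie-break order", {
  inst <- rand_instance(20, L = 3, days = 5, totcap = 9, seed = 7)
  obj <- objective_spec("RTT+D+R")
  a <- solve_schedule(inst, obj)
  b <- solve_schedule(inst, obj)
  expect_identical(a$assignments, b$assignments)

  # identical patients: the tie must resolve by ascending patient id
  ties <- tiny_instance(rtt = c(5, 5, 5), risk = rep("R2", 3),
                        cap = matrix(2, 1, 1))
  sch <- solve_schedule(ties, objective_spec("RTT"))
  expect_setequal(sch$assignments$patient_id, c("p01", "p02"))
  expect_equal(sch$assignments$day[order(sch$assignments$patient_id)],
               c(1L, 1L))
})

test_that("component dominance: each base objective is maximized by its own row", {
  inst <- rand_instance(40, L = 3, days = 6, totcap = 18, seed = 31)
  sw <- objective_sweep(inst)
  expect_equal(which.max(sw$total_rtt_scheduled), match("RTT", sw$objective))
  expect_equal(which.max(sw$total_distance_scheduled), match("D", sw$objective))
  expect_equal(which.max(sw$total_risk_scheduled), match("R", sw$objective))
})

test_that("check_feasibility reports each violated constraint", {
  inst <- tiny_instance(rtt = c(2, 3, 4), risk = rep("R2", 3),
                        cap = matrix(2, 1, 2))
  # double booking of one patient
  dbl <- as_schedule(inst, data.frame(patient_id = c("p01", "p01"),
                                      clinic = "A", day = c(1, 2)))
  expect_match(check_feasibility(inst, dbl), "more than once", all = FALSE)
  # overfull cell, named
  full <- as_schedule(inst, data.frame(patient_id = c("p01", "p02", "p03"),
                                       clinic = "A", day = 1))
  expect_match(check_feasibility(inst, full),
               "capacity exceeded at clinic 'A', day 1", all = FALSE)
  # unknown references are violations, not exceptions
  odd <- as_schedule(inst, data.frame(patient_id = "ghost",
                                      clinic = "Z", day = 99))
  v <- check_feasibility(inst, odd)
  expect_match(v, "unknown patient", all = FALSE)
  expect_match(v, "unknown clinic", all = FALSE)
  expect_match(v, "outside horizon", all = FALSE)
  # solver output is always clean
  sch <- solve_schedule(inst, objective_spec("RTT"))
  expect_identical(check_feasibility(inst, sch), character(0))
})

test_that("empty cohorts and zero-capacity calendars yield the empty schedule", {
  none <- tiny_instance(rtt = numeric(), risk = character(),
                        cap = matrix(1, 1, 2))
  sch <- solve_schedule(none, objective_spec("RTT"))
  expect_equal(nrow(sch$assignments), 0L)
  expect_equal(sch$objective_value, 0)

  nocap <- tiny_instance(rtt = c(1, 2), risk = c("R1", "R2"),
                         cap = matrix(0, 1, 2))
  sch <- solve_schedule(nocap, objective_spec("R"))
  expect_equal(nrow(sch$assignments), 0L)
  expect_setequal(sch$unscheduled, c("p01", "p02"))
})
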