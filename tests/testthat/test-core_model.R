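# Domain types and objective-coefficient assembly.

test_that("risk weighting enforces strictly decreasing positive scores", {
  w <- risk_weights()
  expect_equal(unname(w[c("R1", "R2", "R3")]), c(1000, 10, 1))
  expect_error(risk_weights(10, 10, 1), "R1 > R2 > R3")
  expect_error(risk_weights(1, 10, 1000), "R1 > R2 > R3")
  expect_error(risk_weights(1000, 10, 0), "R1 > R2 > R3")
  expect_silent(risk_weights(3, 2, 1))
})

test_that("objective labels map to 0/1 weight vectors and degenerate specs are rejected", {
  for (lbl in objective_labels()) {
    o <- objective_spec(lbl)
    expect_equal(o$w_rtt, as.numeric(grepl("RTT", lbl)), info = lbl)
    expect_equal(o$w_dist, as.numeric(grepl("D", lbl)), info = lbl)
    expect_equal(o$w_risk, as.numeric(grepl("(^|\\+)R($|\\+)", lbl)), info = lbl)
  }
  expect_equal(objective_spec("rtt+d")$label, "RTT+D")   # case-insensitive
  expect_equal(objective_spec(weights = c(1, 1, 0))$label, "RTT+D")
  expect_equal(objective_spec(weights = c(2, 0.5, 1))$label, "custom")
  expect_error(objective_spec(weights = c(0, 0, 0)), "strictly positive")
  expect_error(objective_spec(weights = c(1, -1, 0)), "non-negative")
  expect_error(objective_spec("RTT", weights = c(1, 0, 0)), "not both")
  expect_error(objective_spec("bogus"), "unknown objective label")
})

test_that("coefficients follow w_rtt*RTT + w_risk*R + w_dist*D at every clinic", {
  inst <- tiny_instance(rtt = c(10, 5), risk = c("R1", "R2"),
                        cap = matrix(1, 2, 3),
                        dist = matrix(c(7, 7, 2, 9), 2, 2, byrow = TRUE))
  # RTT-only: clinic-independent, equal to RTT
  cf <- build_coefficients(inst, objective_spec(weights = c(1, 0, 0)))
  expect_equal(unname(cf[1, ]), c(10, 10))
  # equal weights: 5 (RTT) + 10 (R2) + dist
  cf <- build_coefficients(inst, objective_spec("RTT+D+R"))
  expect_equal(cf["p02", "A"], 5 + 10 + 2)
  expect_equal(cf["p02", "B"], 5 + 10 + 9)
  # clinic-independent iff w_dist = 0
  cf0 <- build_coefficients(inst, objective_spec("RTT+R"))
  expect_true(all(cf0[, 1] == cf0[, 2]))
})

test_that("coefficients are linear in the weight vector", {
  inst <- rand_instance(15, L = 3, seed = 4)
  w1 <- c(1, 0.5, 2); w2 <- c(0.25, 3, 0)
  cf1 <- build_coefficients(inst, objective_spec(weights = w1))
  cf2 <- build_coefficients(inst, objective_spec(weights = w2))
  cf12 <- build_coefficients(inst, objective_spec(weights = w1 + w2))
  expect_equal(cf12, cf1 + cf2)
})

test_that("coefficients are strictly positive under the generator bounds", {
  inst <- rand_instance(25, seed = 11)
  for (lbl in objective_labels()) {
    cf <- build_coefficients(inst, objective_spec(lbl))
    expect_true(all(cf > 0), info = lbl)
  }
})

test_that("validate_instance reports violations by entity instead of throwing", {
  inst <- tiny_instance(rtt = c(3, 4), risk = c("R1", "R3"),
                        cap = matrix(1, 2, 2))
  expect_identical(validate_instance(inst), character(0))

  dup <- inst
  dup$patients$patient_id <- c("p01", "p01")
  v <- validate_instance(dup)
  expect_length(v, 1L)
  expect_match(v, "duplicate patient id 'p01'")

  miss <- inst
  miss$patients$dist_B <- NULL
  v <- validate_instance(miss)
  expect_match(v, "clinic 'B'", all = FALSE)

  neg <- inst
  neg$patients$rtt_weeks[2] <- -1
  expect_match(validate_instance(neg), "p02.*non-negative", all = FALSE)

  bad <- inst
  bad$patients$risk_category[1] <- "R9"
  expect_match(validate_instance(bad), "R9", all = FALSE)

  # a distance column for a clinic the calendar does not know
  extra <- inst
  extra$patients$dist_Z <- 5
  expect_match(validate_instance(extra), "dist_Z", all = FALSE)
})
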