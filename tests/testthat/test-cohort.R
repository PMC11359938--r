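test_that("transition matrix degenerates correctly at the edges", {
  p <- default_parameters()
  bands <- age_bands()$label
  zero_inc <- p
  for (b in bands) {
    zero_inc <- param_set(zero_inc,
                          paste0("epidemiology.hz_incidence.", b), 0)
  }
  zero_inc <- param_set(zero_inc, "epidemiology.p_recurrence", 0)
  M <- build_transition_matrix(zero_inc, "NoVaccination", 60, 0)
  q <- zero_inc$epidemiology$all_cause_mortality[["60"]]
  expect_equal(unname(M["Healthy", c("Healthy", "Dead")]), c(1 - q, q))
  expect_equal(M["Healthy", "AcuteHZ"], 0)

  # certain death sends every row to Dead
  certain <- p
  certain$epidemiology$all_cause_mortality[] <- 1
  M1 <- build_transition_matrix(certain, "ZVL", 70, 3)
  expect_equal(unname(M1[, "Dead"]), rep(1, 6))

  # full protection zeroes breakthrough incidence
  full_ve <- p
  for (b in bands) {
    full_ve <- param_set(full_ve, paste0("efficacy.anchors.RZV.", b),
                         list(years = c(0, 10), ve = c(1, 1)))
  }
  M2 <- build_transition_matrix(full_ve, "RZV", 60, 5)
  expect_equal(M2["Healthy", "AcuteHZ"], 0)
  expect_gt(build_transition_matrix(p, "RZV", 60, 5)["Healthy", "AcuteHZ"], 0)
})

test_that("rows sum to one for arbitrary valid parameters", {
  for (seed in 1:25) {
    p <- make_synthetic_parameters(seed)
    strategy <- sample(c("NoVaccination", "ZVL", "RZV"), 1)
    age <- sample(c(50, 60, 70, 80), 1)
    cycle <- sample(0:39, 1)
    M <- build_transition_matrix(p, strategy, age, cycle)
    expect_equal(unname(rowSums(M)), rep(1, 6), tolerance = 1e-12)
    expect_true(all(M >= 0 & M <= 1))
  }
})

test_that("inconsistent acute-phase split is reported as a parameter error", {
  p <- default_parameters()
  p <- param_set(p, "epidemiology.p_phn_given_hz.60-69", 0.7)
  p <- param_set(p, "epidemiology.p_other_comp_given_hz.60-69", 0.5)
  expect_error(build_transition_matrix(p, "NoVaccination", 60, 0),
               "AcuteHZ row")
})

test_that("an event-free cohort accrues only background utility", {
  p <- default_parameters()
  for (b in age_bands()$label) {
    p <- param_set(p, paste0("epidemiology.hz_incidence.", b), 0)
  }
  p <- param_set(p, "epidemiology.p_recurrence", 0)
  p$epidemiology$all_cause_mortality[] <- 0
  tr <- run_cohort(p, "NoVaccination", 50)
  H <- p$economics$horizon
  expect_equal(sum(tr$cost_stream), 0)
  u <- vapply(0:(H - 1), function(t) {
    zostercea:::.u_healthy_at(p, 50 + t)
  }, 0)
  expect_equal(tr$qaly_stream[1:H], u)
  expect_equal(tr$qaly_stream[H + 1], 0)
})

test_that("occupancy starts as a unit mass and is conserved", {
  p <- make_synthetic_parameters(3)
  tr <- run_cohort(p, "RZV", 50)
  expect_equal(unname(tr$occupancy[1, ]), c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(rowSums(tr$occupancy)),
               rep(1, p$economics$horizon + 1), tolerance = 1e-10)
  expect_true(all(tr$cost_stream >= 0))
  expect_true(all(tr$qaly_stream >= 0))
})

test_that("matrix recursion equals exhaustive path enumeration (toy horizon)", {
  for (seed in c(1, 2, 3)) {
    p <- short_horizon_params(make_synthetic_parameters(seed), 3)
    for (strategy in c("NoVaccination", "RZV")) {
      tr <- run_cohort(p, strategy, 60)
      mats <- lapply(0:2, function(t) {
        build_transition_matrix(p, strategy, 60, t)
      })
      expect_equal(unname(tr$occupancy), oracle_occupancy(mats),
                   tolerance = 1e-12)
    }
  }
})

test_that("vaccination costs at cycle 0 follow the dose schedule", {
  p <- default_parameters()
  tr <- run_cohort(p, "RZV", 60)
  expect_equal(tr$cost_stream[1, "vaccine"] + tr$cost_stream[1, "admin"],
               2 * (453.55 + 4.24))
  tr_z <- run_cohort(p, "ZVL", 60)
  expect_equal(tr_z$cost_stream[1, "vaccine"] + tr_z$cost_stream[1, "admin"],
               194.28 + 4.24)
  tr_n <- run_cohort(p, "NoVaccination", 60)
  expect_equal(tr_n$cost_stream[1, "vaccine"], 0)
  # partial two-dose compliance: completers pay 2 doses, the rest 1
  p6 <- param_set(p, "economics.compliance_two_dose", 0.6)
  tr6 <- run_cohort(p6, "RZV", 60)
  expect_equal(tr6$cost_stream[1, "vaccine"],
               (0.6 * 2 + 0.4 * 1) * 453.55)
})

test_that("summaries discount costs and QALYs but not event counts", {
  p <- default_parameters()
  tr <- run_cohort(p, "ZVL", 60)
  # r = 0: discounted totals equal raw sums
  p0 <- param_set(p, "economics.discount_rate", 0)
  s0 <- summarize_trace(tr, p0)
  expect_equal(s0$total_cost_per_1000, 1000 * sum(tr$cost_stream))
  expect_equal(s0$total_qalys_per_1000, 1000 * sum(tr$qaly_stream))
  # a single cost of 105 at cycle 1 discounts to 100 at 5%
  toy <- tr
  toy$cost_stream[] <- 0
  toy$cost_stream[2, "direct_medical"] <- 105
  toy$qaly_stream[] <- 0
  toy$new_hz_episodes[] <- 0
  toy$new_phn_cases[] <- 0
  s <- summarize_trace(toy, p)
  expect_equal(s$total_cost_per_1000, 100 * 1000, tolerance = 1e-12)
  # a cost at cycle 0 is not discounted
  toy$cost_stream[] <- 0
  toy$cost_stream[1, "vaccine"] <- 42
  expect_equal(summarize_trace(toy, p)$total_cost_per_1000, 42 * 1000)
  # event counts are undiscounted
  s1 <- summarize_trace(tr, p)
  expect_equal(s1$cases_per_1000, 1000 * sum(tr$new_hz_episodes))
})

test_that("vaccination averts cases and gains QALYs; discounting is monotone", {
  for (seed in c(4, 8)) {
    p <- make_synthetic_parameters(seed)
    none <- summarize_trace(run_cohort(p, "NoVaccination", 60), p)
    for (s in c("ZVL", "RZV")) {
      vac <- summarize_trace(run_cohort(p, s, 60), p)
      expect_lte(vac$cases_per_1000, none$cases_per_1000)
      expect_gte(vac$total_qalys_per_1000, none$total_qalys_per_1000)
    }
  }
  p <- default_parameters()
  tr <- run_cohort(p, "RZV", 50)
  rates <- c(0, 0.02, 0.05, 0.1)
  totals <- vapply(rates, function(r) {
    pr <- param_set(p, "economics.discount_rate", r)
    s <- summarize_trace(tr, pr)
    c(s$total_cost_per_1000, s$total_qalys_per_1000)
  }, numeric(2))
  expect_true(all(diff(totals[1, ]) <= 0))
  expect_true(all(diff(totals[2, ]) <= 0))
})

test_that("trace exports a tidy per-cycle data frame", {
  p <- short_horizon_params(default_parameters(), 5)
  tr <- run_cohort(p, "RZV", 60)
  df <- as.data.frame(tr)
  expect_identical(nrow(df), 6L)
  expect_true(all(c("cycle", "age", "occ_Healthy", "occ_Dead",
                    "new_hz_episodes", "cost_vaccine", "qalys") %in%
                    names(df)))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  expect_equal(nrow(utils::read.csv(f)), 6L)
})

test_that("half-cycle correction averages adjacent occupancies", {
  p <- default_parameters()
  ph <- param_set(p, "model.half_cycle_correction", TRUE)
  q <- run_cohort(p, "NoVaccination", 60)$qaly_stream
  qh <- run_cohort(ph, "NoVaccination", 60)$qaly_stream
  expect_lt(sum(qh), sum(q))  # mortality makes the average smaller
})
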