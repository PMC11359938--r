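test_that("tornado bars collapse when bounds are degenerate or inert", {
  p <- short_horizon_params(default_parameters(), 15)
  base_inc <- unname(p$epidemiology$hz_incidence["60-69"])
  p$owsa_spec <- list(
    list(path = "epidemiology.hz_incidence.60-69", low = base_inc,
         high = base_inc),
    # the exchange rate never enters the model after load: inert parameter
    list(path = "costs.cny_per_usd", low = 6, high = 8)
  )
  tor <- one_way_tornado(p, "RZV", start_age = 60, top_n = Inf)
  expect_equal(tor$bar_width, c(0, 0))
})

test_that("tornado entries are sorted by bar width and truncated", {
  p <- short_horizon_params(default_parameters(), 15)
  tor <- one_way_tornado(p, "RZV", start_age = 60, top_n = 6)
  expect_identical(nrow(tor), 6L)
  expect_true(all(diff(tor$bar_width) <= 0))
  expect_true(is.finite(attr(tor, "base_icer")))
})

test_that("widening a parameter's range widens its tornado bar", {
  p <- short_horizon_params(default_parameters(), 15)
  base_inc <- unname(p$epidemiology$hz_incidence["60-69"])
  narrow <- wide <- p
  narrow$owsa_spec <- list(list(path = "epidemiology.hz_incidence.60-69",
                                low = base_inc * 0.9, high = base_inc * 1.1))
  wide$owsa_spec <- list(list(path = "epidemiology.hz_incidence.60-69",
                              low = base_inc * 0.6, high = base_inc * 1.4))
  w_narrow <- one_way_tornado(narrow, "RZV", 60)$bar_width
  w_wide <- one_way_tornado(wide, "RZV", 60)$bar_width
  expect_gt(w_wide, w_narrow)
})

test_that("unknown tornado parameter paths raise a configuration error", {
  p <- default_parameters()
  p$owsa_spec <- list(list(path = "costs.not_a_cost", low = 0, high = 1))
  expect_error(one_way_tornado(p, "RZV", 60), "not found")
})

test_that("PSA with point distributions is the identity and steps its CEAC", {
  p <- short_horizon_params(default_parameters(), 15)
  p$psa_spec <- lapply(p$psa_spec[1:5], function(e) {
    list(path = e$path, family = "point")
  })
  psa <- run_psa(p, start_age = 60, n_draws = 20, seed = 4,
                 wtp_grid = seq(0, 5e5, length.out = 21))
  # every draw identical
  expect_equal(unname(vapply(psa$draws[-1], function(col) {
    max(col) - min(col)
  }, 0)), rep(0, 6))
  # CEAC probabilities are 0/1 and sum to 1 at every wtp
  expect_true(all(psa$ceac$probability %in% c(0, 1)))
  sums <- tapply(psa$ceac$probability, psa$ceac$wtp, sum)
  expect_equal(unname(as.numeric(sums)), rep(1, 21))
  # wtp = 0 prefers the least-cost strategy with certainty
  pref0 <- psa_preference(psa, 0)
  costs <- colMeans(psa$draws[, paste0("cost_", names(pref0))])
  expect_equal(unname(pref0[which.min(costs)]), 1)
  # as wtp grows, the max-QALY strategy is preferred with certainty
  qalys <- colMeans(psa$draws[, paste0("qaly_", names(pref0))])
  pref_inf <- psa_preference(psa, 1e9)
  expect_equal(unname(pref_inf[which.max(qalys)]), 1)
})

test_that("a fixed seed makes the PSA bit-reproducible", {
  p <- short_horizon_params(default_parameters(), 10)
  a <- run_psa(p, start_age = 60, n_draws = 8, seed = 99)
  b <- run_psa(p, start_age = 60, n_draws = 8, seed = 99)
  expect_identical(a, b)
  c2 <- run_psa(p, start_age = 60, n_draws = 8, seed = 100)
  expect_false(identical(a$draws, c2$draws))
})

test_that("compliance 1.0 reproduces the base-case RZV ICER exactly", {
  p <- short_horizon_params(default_parameters(), 15)
  fit <- zoster_cea(p, ages = 60)
  base_icer <- fit$runs[["60"]]$comparisons$RZV$icer
  tab <- compliance_scenario(p, rates = c(0.5, 1.0), ages = 60)
  expect_equal(tab$icer[tab$compliance == 1.0], base_icer)
})

test_that("with equal one- and two-dose efficacy, lower compliance lowers ICER", {
  p <- short_horizon_params(default_parameters(), 15)
  p <- param_set(p, "efficacy.rzv_one_dose_factor", 1.0)
  tab <- compliance_scenario(p, rates = seq(0.2, 1, by = 0.2), ages = 60)
  # benefits constant, dose costs rise with compliance
  expect_true(all(diff(tab$icer) > 0))
})

test_that("compliance rates outside [0, 1] are rejected", {
  expect_error(compliance_scenario(default_parameters(), rates = c(0.5, 1.2)),
               "\\[0, 1\\]")
})

test_that("price threshold: identical arms cross where total costs equalize", {
  p <- default_parameters()
  # make RZV protection identical to ZVL's and RZV cheap: the NMB gap is
  # then purely monetary and the crossing price equalizes total costs
  p$efficacy$anchors$RZV <- p$efficacy$anchors$ZVL
  p <- param_set(p, "costs.price_rzv_dose", 50)
  th <- zvl_price_threshold(p, start_age = 60)
  expect_identical(th$status, "ok")
  # ZVL at p*: one dose + admin equals RZV's two doses + admin
  expect_equal(th$threshold_price + 4.24, 2 * (50 + 4.24), tolerance = 1e-6)
  expect_equal(th$pct_reduction_from_base,
               100 * (194.28 - th$threshold_price) / 194.28)
})

test_that("closed-form threshold agrees with bisection and zeroes the NMB gap", {
  p <- threshold_scenario()
  wtp <- p$economics$wtp
  th <- zvl_price_threshold(p, start_age = 60)
  expect_identical(th$status, "ok")
  nmb_gap <- function(price) {
    pp <- param_set(p, "costs.price_zvl_dose", price)
    rz <- summarize_trace(run_cohort(pp, "RZV", 60), pp)
    zv <- summarize_trace(run_cohort(pp, "ZVL", 60), pp)
    (wtp * zv$total_qalys_per_1000 - zv$total_cost_per_1000) -
      (wtp * rz$total_qalys_per_1000 - rz$total_cost_per_1000)
  }
  # independent root: bisection on the NMB gap
  root <- stats::uniroot(nmb_gap, c(0, p$costs$price_zvl_dose),
                         tol = 1e-9)$root
  expect_equal(th$threshold_price, root, tolerance = 1e-6)
  expect_lt(abs(nmb_gap(th$threshold_price)), 1e-6 * wtp)
})

test_that("threshold precondition and no-crossing cases are signalled", {
  # packaged base: ZVL already has the higher NMB, precondition fails
  expect_error(zvl_price_threshold(default_parameters(), 60),
               "precondition")
  # RZV vastly better: no nonnegative ZVL price can catch up
  p <- threshold_scenario()
  p <- param_set(p, "costs.price_rzv_dose", 0)
  p <- param_set(p, "efficacy.anchors.ZVL.60-69",
                 list(years = c(0, 11), ve = c(0.01, 0)))
  th <- zvl_price_threshold(p, 60)
  expect_identical(th$status, "not achievable by price alone")
  expect_true(is.na(th$threshold_price))
})
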