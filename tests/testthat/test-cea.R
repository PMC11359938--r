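test_that("ICER classifies the four quadrants", {
  expect_equal(compute_icer(100, 10), list(status = "icer", icer = 10))
  expect_identical(compute_icer(-10, 5)$status, "comparator_dominant")
  expect_identical(compute_icer(10, -5)$status, "comparator_dominated")
  expect_identical(compute_icer(10, 0)$status, "undefined")
  expect_true(is.na(compute_icer(10, 0)$icer))
})

test_that("ICER is invariant to joint scaling (per-1000 reporting)", {
  set.seed(1)
  for (i in 1:20) {
    dc <- rnorm(1, 0, 1e5)
    dq <- rnorm(1, 0, 30)
    k <- runif(1, 1e-3, 1e3)
    a <- compute_icer(dc, dq)
    b <- compute_icer(k * dc, k * dq)
    expect_identical(a$status, b$status)
    if (a$status == "icer") expect_equal(a$icer, b$icer)
  }
})

test_that("WTP decisions follow net monetary benefit and are monotone", {
  cmp <- list(delta_cost = 108723, delta_qaly = 31.72)
  expect_true(decide_at_wtp(cmp, 12681))
  expect_false(decide_at_wtp(list(delta_cost = 56226, delta_qaly = 3.08),
                             12681))
  # dominant comparator is cost-effective at any threshold
  dom <- list(delta_cost = -5, delta_qaly = 2)
  for (w in c(1, 100, 1e6)) expect_true(decide_at_wtp(dom, w))
  # monotone in wtp for positive delta_qaly
  wtps <- c(100, 1000, 5000, 20000, 1e5)
  dec <- vapply(wtps, function(w) decide_at_wtp(cmp, w), NA)
  expect_true(all(diff(as.integer(dec)) >= 0))
  expect_error(decide_at_wtp(cmp, 0), "> 0")
})

test_that("averted percentages report rounded and unrounded values", {
  expect_equal(averted_pct(287, 164)$rounded, 43)
  expect_equal(averted_pct(287, 164)$pct, 100 * 123 / 287)
  expect_equal(averted_pct(100, 100)$rounded, 0)
  expect_identical(averted_pct(0, 5)$status, "undefined")
  # ties round away from zero
  expect_equal(averted_pct(200, 101)$rounded, 50)
  expect_equal(round_half_away(c(0.5, -0.5, 2.5)), c(1, -1, 3))
})

test_that("frontier flags dominance, extended dominance, and ties stably", {
  mk <- function(strategy, cost, qalys) {
    structure(list(strategy = strategy, start_age = 60,
                   cases_per_1000 = 0, phn_per_1000 = 0,
                   total_cost_per_1000 = cost, total_qalys_per_1000 = qalys),
              class = "strategy_result")
  }
  # identical pair: the second (input order) is flagged by the tie rule
  fr <- cea_frontier(list(mk("A", 100, 10), mk("B", 100, 10)), wtp = 1000)
  expect_identical(fr$strategy[fr$dominated], "B")
  # middle point above the chord is extended-dominated
  fr2 <- cea_frontier(list(mk("cheap", 0, 0), mk("middle", 60, 1),
                           mk("dear", 100, 10)), wtp = 1e4)
  expect_true(fr2$extended_dominated[fr2$strategy == "middle"])
  # brute-force oracle: a non-dominated strategy is off the frontier iff it
  # is never NMB-optimal at any nonnegative willingness-to-pay
  set.seed(33)
  for (rep in 1:20) {
    res <- lapply(1:4, function(i) {
      mk(paste0("S", i), runif(1, 0, 100), runif(1, 0, 10))
    })
    fr3 <- cea_frontier(res, wtp = 5000)
    costs <- vapply(res, `[[`, 0, "total_cost_per_1000")
    qalys <- vapply(res, `[[`, 0, "total_qalys_per_1000")
    # exact: preference regions are delimited by pairwise NMB crossings, so
    # checking every region midpoint (plus endpoints) is exhaustive
    cross <- c()
    for (i in 1:3) for (j in (i + 1):4) {
      if (qalys[i] != qalys[j]) {
        w <- (costs[i] - costs[j]) / (qalys[i] - qalys[j])
        if (w > 0) cross <- c(cross, w)
      }
    }
    cross <- sort(unique(cross))
    wgrid <- unique(c(0, cross, (utils::head(cross, -1) +
                                   utils::tail(cross, -1)) / 2,
                      max(cross, 1) * 2))
    ever_best <- rep(FALSE, 4)
    for (w in wgrid) {
      nmb <- w * qalys - costs
      ever_best[nmb >= max(nmb) - 1e-9] <- TRUE
    }
    on_front <- fr3$on_frontier[match(paste0("S", 1:4), fr3$strategy)]
    expect_identical(on_front, ever_best)
  }
  # surviving set is invariant to input order
  res <- list(mk("A", 10, 1), mk("B", 50, 6), mk("C", 30, 5))
  f1 <- cea_frontier(res, 1e4)
  f2 <- cea_frontier(rev(res), 1e4)
  expect_setequal(f1$strategy[f1$on_frontier], f2$strategy[f2$on_frontier])
})

test_that("published results table puts RZV on the 60-year frontier", {
  mk <- function(strategy, cost, qalys) {
    structure(list(strategy = strategy, start_age = 60,
                   cases_per_1000 = 0, phn_per_1000 = 0,
                   total_cost_per_1000 = cost, total_qalys_per_1000 = qalys),
              class = "strategy_result")
  }
  fr <- cea_frontier(list(mk("NoVaccination", 130046, 11467),
                          mk("ZVL", 178670, 11479),
                          mk("RZV", 238768, 11498)), wtp = 12681)
  expect_true(fr$on_frontier[fr$strategy == "RZV"])
  expect_true(fr$extended_dominated[fr$strategy == "ZVL"])
  expect_true(fr$optimal_at_wtp[fr$strategy == "RZV"])
})

test_that("the fitted analysis object exposes a tidy results table", {
  p <- short_horizon_params(default_parameters(), 10)
  fit <- zoster_cea(p, ages = c(60, 70))
  df <- as.data.frame(fit)
  expect_identical(nrow(df), 6L)
  expect_identical(df$strategy[1:3], c("NoVaccination", "ZVL", "RZV"))
  expect_true(all(is.na(df$icer[df$strategy == "NoVaccination"])))
  expect_output(print(fit), "WTP")
  expect_output(summary(fit), "averts")
  cmp <- fit$runs[["60"]]$comparisons$RZV
  expect_equal(cmp$delta_cost,
               df$incr_cost[df$age == 60 & df$strategy == "RZV"],
               tolerance = 1e-6)
})
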