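# Annual-cycle Markov cohort engine.
#
# States: Healthy, AcuteHZ, PHN, OtherComplication, HZResolved, Dead.
# Competing risks: all-cause mortality at the attained age is applied first
# each cycle; disease transitions occur among survivors (multiplicative
# composition), so every row sums to 1 by construction. Death from zoster
# itself applies only during AcuteHZ via the per-episode case fatality.

#' Per-cycle transition matrix for one strategy
#'
#' Builds the 6x6 transition probability matrix for a given cycle of the
#' simulation. The Healthy to AcuteHZ probability is the band-specific
#' incidence at the attained age times `(1 - VE)`, where VE is the strategy's
#' (possibly waned) vaccine efficacy at `cycle` years since vaccination.
#' Acute zoster resolves in one cycle, splitting into PHN, other
#' complications, recovery, or zoster death; PHN and other complications exit
#' to the resolved state with configurable per-cycle probabilities
#' (`model.phn_exit_prob`, `model.comp_exit_prob`, both 1 by default, i.e.
#' one-cycle dwell). Recovered individuals can experience recurrence, again
#' scaled by `(1 - VE)`.
#'
#' @param params A `zoster_params` object.
#' @param strategy One of `"NoVaccination"`, `"ZVL"`, `"RZV"`.
#' @param start_age Age at vaccination / model entry (>= 50).
#' @param cycle Cycle index, 0-based (years since model entry).
#' @param curves Optional pre-built efficacy curves (internal caching); when
#'   `NULL` they are fitted from the parameter set's anchors.
#' @return A 6x6 matrix with rows summing to 1, dimnames the state names.
#' @export
build_transition_matrix <- function(params, strategy, start_age, cycle,
                                    curves = NULL) {
  strategy <- .match_strategy(strategy)
  if (cycle < 0 || cycle >= params$economics$horizon) {
    stop("cycle must satisfy 0 <= cycle < horizon", call. = FALSE)
  }
  if (is.null(curves)) curves <- .strategy_curves(params, strategy, start_age)
  age <- start_age + cycle
  b <- band_of(age)
  epi <- params$epidemiology

  q <- .mortality_at(params, age)                    # all-cause, attained age
  ve <- .strategy_ve(params, strategy, curves, cycle)
  h <- epi$hz_incidence[[b]] * (1 - ve)              # breakthrough incidence
  cf <- epi$hz_case_fatality[[b]]
  mult <- if (strategy == "NoVaccination") 1 else
    params$efficacy$phn_multiplier[[strategy]]
  p_phn <- min(epi$p_phn_given_hz[[b]] * mult, 1)
  p_comp <- epi$p_other_comp_given_hz[[b]]
  if (p_phn + p_comp > 1) {
    stop("AcuteHZ row: p_phn_given_hz + p_other_comp_given_hz > 1 in band ",
         b, call. = FALSE)
  }
  r <- epi$p_recurrence * (1 - ve)
  e_phn <- params$model$phn_exit_prob
  e_comp <- params$model$comp_exit_prob

  s <- .zoster_states
  M <- matrix(0, 6, 6, dimnames = list(s, s))
  M["Healthy", "AcuteHZ"] <- (1 - q) * h
  M["Healthy", "Healthy"] <- (1 - q) * (1 - h)
  M["Healthy", "Dead"] <- q

  surv <- (1 - q) * (1 - cf)
  M["AcuteHZ", "PHN"] <- surv * p_phn
  M["AcuteHZ", "OtherComplication"] <- surv * p_comp
  M["AcuteHZ", "HZResolved"] <- surv * (1 - p_phn - p_comp)
  M["AcuteHZ", "Dead"] <- q + (1 - q) * cf

  M["PHN", "HZResolved"] <- (1 - q) * e_phn
  M["PHN", "PHN"] <- (1 - q) * (1 - e_phn)
  M["PHN", "Dead"] <- q

  M["OtherComplication", "HZResolved"] <- (1 - q) * e_comp
  M["OtherComplication", "OtherComplication"] <- (1 - q) * (1 - e_comp)
  M["OtherComplication", "Dead"] <- q

  M["HZResolved", "AcuteHZ"] <- (1 - q) * r
  M["HZResolved", "HZResolved"] <- (1 - q) * (1 - r)
  M["HZResolved", "Dead"] <- q

  M["Dead", "Dead"] <- 1
  M
}

#' Run the cohort simulation for one strategy
#'
#' Propagates a unit cohort starting in Healthy at `start_age` through
#' `horizon` annual cycles, recording state occupancy, incident zoster
#' episodes (including recurrences), incident PHN cases, undiscounted cost
#' streams by category and undiscounted QALY streams.
#'
#' Vaccination costs are charged at cycle 0: two RZV doses weighted by
#' two-dose compliance (non-completers pay one dose), one ZVL dose, nothing
#' for no vaccination; each dose carries the administration fee. Disease
#' costs attach to the cycles in which the corresponding states are occupied.
#' QALYs accrue for cycles 0 to horizon-1 using the attained-age background
#' utility for Healthy/HZResolved and the state utilities otherwise; an
#' optional half-cycle correction (`model.half_cycle_correction`) averages
#' adjacent occupancies.
#'
#' @inheritParams build_transition_matrix
#' @return An object of class `cohort_trace`: list with `occupancy`
#'   (`(horizon+1) x 6` matrix), `new_hz_episodes`, `new_phn_cases`,
#'   `cost_stream` (`(horizon+1) x 5`, categories vaccine/admin/
#'   direct_medical/non_medical/indirect), `qaly_stream`, plus the strategy,
#'   start age and discount rate used.
#' @examples
#' p <- default_parameters()
#' tr <- run_cohort(p, "RZV", 60)
#' summarize_trace(tr, p)
#' @export
run_cohort <- function(params, strategy, start_age) {
  strategy <- .match_strategy(strategy)
  if (start_age < 50) stop("start_age must be >= 50", call. = FALSE)
  H <- params$economics$horizon
  curves <- .strategy_curves(params, strategy, start_age)
  s <- .zoster_states
  categories <- c("vaccine", "admin", "direct_medical", "non_medical",
                  "indirect")

  occ <- matrix(0, H + 1L, 6L, dimnames = list(0:H, s))
  occ[1L, "Healthy"] <- 1
  new_hz <- numeric(H + 1L)
  new_phn <- numeric(H + 1L)
  cost <- matrix(0, H + 1L, 5L, dimnames = list(0:H, categories))
  qaly <- numeric(H + 1L)

  # vaccination costs, cycle 0 (two RZV doses within two months fall in the
  # first annual cycle)
  cmp <- params$economics$compliance_two_dose
  doses <- switch(strategy, NoVaccination = 0, ZVL = 1,
                  RZV = 2 * cmp + 1 * (1 - cmp))
  if (doses > 0) {
    cost[1L, "vaccine"] <- doses * switch(strategy, ZVL =
      params$costs$price_zvl_dose, RZV = params$costs$price_rzv_dose)
    cost[1L, "admin"] <- doses * params$costs$cost_admin_dose
    cost[1L, "direct_medical"] <- params$model$vaccine_ae_cost
  }

  for (t in 0:(H - 1L)) {
    M <- build_transition_matrix(params, strategy, start_age, t,
                                 curves = curves)
    prev <- occ[t + 1L, ]
    nxt <- as.numeric(prev %*% M)
    occ[t + 2L, ] <- nxt
    new_hz[t + 2L] <- prev[["Healthy"]] * M["Healthy", "AcuteHZ"] +
      prev[["HZResolved"]] * M["HZResolved", "AcuteHZ"]
    new_phn[t + 2L] <- prev[["AcuteHZ"]] * M["AcuteHZ", "PHN"]
  }

  cc <- params$costs
  for (t in 0:H) {
    o <- occ[t + 1L, ]
    cost[t + 1L, "direct_medical"] <- cost[t + 1L, "direct_medical"] +
      o[["AcuteHZ"]] * cc$cost_hz_episode +
      o[["PHN"]] * cc$cost_phn +
      o[["OtherComplication"]] * cc$cost_other_comp
    cost[t + 1L, "non_medical"] <- o[["AcuteHZ"]] * cc$cost_nonmedical
    cost[t + 1L, "indirect"] <- o[["AcuteHZ"]] * cc$cost_indirect
  }

  uu <- params$utilities
  state_u <- function(t) {
    uh <- .u_healthy_at(params, start_age + t)
    # disease states cannot exceed the attained-age background utility
    c(uh, min(uu$u_hz, uh), min(uu$u_phn, uh), min(uu$u_other_comp, uh),
      uh, 0)
  }
  hcc <- params$model$half_cycle_correction
  for (t in 0:(H - 1L)) {
    o <- if (hcc) (occ[t + 1L, ] + occ[t + 2L, ]) / 2 else occ[t + 1L, ]
    qaly[t + 1L] <- sum(o * state_u(t))
  }
  if (strategy != "NoVaccination") {
    qaly[1L] <- qaly[1L] - params$model$vaccine_disutility
  }

  out <- list(
    strategy = strategy, start_age = start_age,
    discount_rate = params$economics$discount_rate,
    occupancy = occ, new_hz_episodes = new_hz, new_phn_cases = new_phn,
    cost_stream = cost, qaly_stream = qaly
  )
  class(out) <- "cohort_trace"
  out
}

#' Lifetime per-thousand summary of a cohort trace
#'
#' Costs and QALYs are discounted at the parameter set's annual rate
#' (`1/(1+r)^t`); episode and PHN counts are undiscounted sums. Everything is
#' scaled to a cohort of 1000 (the engine itself runs a unit cohort).
#'
#' @param trace A `cohort_trace`.
#' @param params The `zoster_params` the trace was run with.
#' @return An object of class `strategy_result`: list with `strategy`,
#'   `start_age`, `cases_per_1000`, `phn_per_1000`, `total_cost_per_1000`,
#'   `total_qalys_per_1000`.
#' @export
summarize_trace <- function(trace, params) {
  stopifnot(inherits(trace, "cohort_trace"))
  r <- params$economics$discount_rate
  t <- seq_len(nrow(trace$cost_stream)) - 1L
  disc <- 1 / (1 + r)^t
  out <- list(
    strategy = trace$strategy,
    start_age = trace$start_age,
    cases_per_1000 = 1000 * sum(trace$new_hz_episodes),
    phn_per_1000 = 1000 * sum(trace$new_phn_cases),
    total_cost_per_1000 = 1000 * sum(rowSums(trace$cost_stream) * disc),
    total_qalys_per_1000 = 1000 * sum(trace$qaly_stream * disc)
  )
  class(out) <- "strategy_result"
  out
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("%s cohort entering at age %d (per 1000 persons, lifetime):\n",
              x$strategy, x$start_age))
  cat(sprintf("  HZ episodes: %.1f   PHN cases: %.1f\n",
              x$cases_per_1000, x$phn_per_1000))
  cat(sprintf("  Discounted cost: USD %.0f   Discounted QALYs: %.1f\n",
              x$total_cost_per_1000, x$total_qalys_per_1000))
  invisible(x)
}

#' @export
print.cohort_trace <- function(x, ...) {
  H <- nrow(x$occupancy) - 1L
  cat(sprintf("Cohort trace: %s, entry age %d, %d annual cycles\n",
              x$strategy, x$start_age, H))
  alive <- 1 - x$occupancy[H + 1L, "Dead"]
  cat(sprintf("  Survivors at horizon: %.1f%%   Lifetime HZ episodes/person: %.3f\n",
              100 * alive, sum(x$new_hz_episodes)))
  invisible(x)
}

#' Cycle-by-cycle view of a cohort trace
#'
#' @param x A `cohort_trace`.
#' @param row.names,optional,... Passed through for S3 compatibility; unused.
#' @return A data.frame with one row per cycle: state occupancies, new
#'   events, cost categories and QALYs (all undiscounted).
#' @export
as.data.frame.cohort_trace <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  df <- data.frame(
    cycle = seq_len(nrow(x$occupancy)) - 1L,
    age = x$start_age + seq_len(nrow(x$occupancy)) - 1L,
    x$occupancy,
    new_hz_episodes = x$new_hz_episodes,
    new_phn_cases = x$new_phn_cases,
    x$cost_stream,
    qalys = x$qaly_stream,
    check.names = FALSE
  )
  names(df)[3:8] <- paste0("occ_", .zoster_states)
  names(df)[11:15] <- paste0("cost_", colnames(x$cost_stream))
  rownames(df) <- NULL
  df
}
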