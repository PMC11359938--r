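# Cost-effectiveness arithmetic: ICERs with dominance classification, net
# monetary benefit, willingness-to-pay decisions, averted-burden percentages,
# and the efficiency frontier.

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' @param delta_cost Incremental cost (comparator minus reference), USD.
#' @param delta_qaly Incremental QALYs (comparator minus reference).
#' @return A list with `status` (`"icer"`, `"comparator_dominant"`,
#'   `"comparator_dominated"`, or `"undefined"`) and `icer` (the ratio when a
#'   ratio is meaningful, otherwise `NA`). The comparator is *dominant* when
#'   it is cheaper and more effective, *dominated* when costlier and less
#'   effective; with zero incremental QALYs the ratio is undefined.
#' @examples
#' compute_icer(108723, 31.72)  # approximately 3428 USD/QALY
#' compute_icer(-10, 5)         # comparator dominant
#' @export
compute_icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) {
    return(list(status = "undefined", icer = NA_real_))
  }
  if (delta_qaly > 0 && delta_cost < 0) {
    return(list(status = "comparator_dominant", icer = NA_real_))
  }
  if (delta_qaly < 0 && delta_cost > 0) {
    return(list(status = "comparator_dominated", icer = NA_real_))
  }
  list(status = "icer", icer = delta_cost / delta_qaly)
}

#' Pairwise strategy comparison
#'
#' @param reference,comparator `strategy_result` objects (the reference is
#'   usually no vaccination).
#' @param wtp Willingness-to-pay threshold, USD per QALY.
#' @return An object of class `cea_comparison`: incremental cost and QALYs,
#'   ICER/dominance status, net monetary benefit at `wtp`
#'   (`wtp * dQALY - dCost`), and the cost-effectiveness decision.
#' @export
compare_pair <- function(reference, comparator, wtp) {
  stopifnot(inherits(reference, "strategy_result"),
            inherits(comparator, "strategy_result"))
  dc <- comparator$total_cost_per_1000 - reference$total_cost_per_1000
  dq <- comparator$total_qalys_per_1000 - reference$total_qalys_per_1000
  ic <- compute_icer(dc, dq)
  out <- list(
    reference = reference$strategy, comparator = comparator$strategy,
    start_age = comparator$start_age,
    delta_cost = dc, delta_qaly = dq,
    status = ic$status, icer = ic$icer,
    wtp = wtp, nmb_at_wtp = wtp * dq - dc,
    cost_effective_at_wtp = wtp * dq - dc > 0
  )
  class(out) <- "cea_comparison"
  out
}

#' Cost-effectiveness decision at a willingness-to-pay threshold
#'
#' A comparator is cost-effective against the reference when its net monetary
#' benefit `wtp * dQALY - dCost` is positive; for the standard north-east
#' quadrant this is equivalent to `ICER < wtp`.
#'
#' @param comparison A `cea_comparison`, or a list with `delta_cost` and
#'   `delta_qaly`.
#' @param wtp Willingness-to-pay, USD per QALY (> 0).
#' @return `TRUE` iff the comparator is cost-effective at `wtp`.
#' @examples
#' cmp <- list(delta_cost = 108723, delta_qaly = 31.72)
#' decide_at_wtp(cmp, 12681)
#' @export
decide_at_wtp <- function(comparison, wtp) {
  if (wtp <= 0) stop("wtp must be > 0", call. = FALSE)
  wtp * comparison$delta_qaly - comparison$delta_cost > 0
}

#' Percentage of disease burden averted
#'
#' @param cases_reference Case count without the intervention (> 0).
#' @param cases_comparator Case count with the intervention.
#' @return List with `pct` (unrounded percentage averted) and `rounded`
#'   (nearest integer, ties away from zero). With a zero reference count the
#'   status is `"undefined"` and both values are `NA`.
#' @examples
#' averted_pct(287, 164)$rounded  # 43
#' @export
averted_pct <- function(cases_reference, cases_comparator) {
  if (cases_reference == 0) {
    return(list(status = "undefined", pct = NA_real_, rounded = NA_real_))
  }
  pct <- 100 * (cases_reference - cases_comparator) / cases_reference
  list(status = "ok", pct = pct, rounded = round_half_away(pct))
}

#' Round half away from zero
#'
#' Commercial rounding used for reported ICERs and percentages (base R's
#' `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cost-effectiveness frontier with extended dominance
#'
#' Orders strategies by cost, flags strictly dominated strategies (no cheaper
#' strategy attains at least their QALYs) and extended-dominated strategies
#' (sequential ICER not decreasing along the frontier), and computes
#' sequential ICERs on the survivors.
#'
#' @param results List of `strategy_result` objects (>= 2).
#' @param wtp Willingness-to-pay used to mark the frontier choice.
#' @return A data.frame sorted by cost with columns `strategy`, `cost`,
#'   `qalys`, `dominated`, `extended_dominated`, `icer_sequential`,
#'   `on_frontier`, `optimal_at_wtp`.
#' @export
cea_frontier <- function(results, wtp) {
  stopifnot(length(results) >= 2)
  df <- data.frame(
    strategy = vapply(results, `[[`, "", "strategy"),
    cost = vapply(results, `[[`, 0, "total_cost_per_1000"),
    qalys = vapply(results, `[[`, 0, "total_qalys_per_1000"),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$cost), , drop = FALSE]  # stable: ties keep input order
  n <- nrow(df)
  df$dominated <- FALSE
  for (i in seq_len(n)) {
    others <- df[-i, , drop = FALSE]
    df$dominated[i] <- any(others$cost <= df$cost[i] &
                             others$qalys >= df$qalys[i] &
                             (others$cost < df$cost[i] |
                                others$qalys > df$qalys[i] |
                                seq_len(n)[-i] < i))
  }
  # extended dominance: iteratively drop strategies whose sequential ICER
  # exceeds that of the next more expensive survivor
  df$extended_dominated <- FALSE
  repeat {
    idx <- which(!df$dominated & !df$extended_dominated)
    if (length(idx) < 3) break
    icers <- diff(df$cost[idx]) / diff(df$qalys[idx])
    bad <- which(icers[-length(icers)] >= icers[-1])
    if (!length(bad)) break
    df$extended_dominated[idx[bad[1] + 1]] <- TRUE
  }
  df$icer_sequential <- NA_real_
  idx <- which(!df$dominated & !df$extended_dominated)
  if (length(idx) > 1) {
    df$icer_sequential[idx[-1]] <- diff(df$cost[idx]) / diff(df$qalys[idx])
  }
  df$on_frontier <- !df$dominated & !df$extended_dominated
  nmb <- wtp * df$qalys - df$cost
  df$optimal_at_wtp <- seq_len(n) == which.max(nmb)
  rownames(df) <- NULL
  df
}

#' Run the full base-case cost-effectiveness analysis
#'
#' The package's main entry point: runs the three strategies (no vaccination,
#' one-dose ZVL, two-dose RZV) through the Markov cohort engine for each
#' vaccination age, and compares each vaccine against no vaccination.
#'
#' @param params A `zoster_params` object; `default_parameters()` if omitted.
#' @param ages Vaccination ages to analyse (one per age band by default).
#' @return An object of class `zoster_cea` with per-age `strategy_result`s,
#'   pairwise comparisons versus no vaccination, the frontier per age, and
#'   the WTP used. Methods: `print`, `summary`, `as.data.frame`, `plot`.
#' @examples
#' fit <- zoster_cea(default_parameters(), ages = 60)
#' fit
#' as.data.frame(fit)
#' @export
zoster_cea <- function(params = default_parameters(),
                       ages = c(50, 60, 70, 80)) {
  stopifnot(inherits(params, "zoster_params"))
  wtp <- params$economics$wtp
  runs <- list()
  for (age in ages) {
    res <- lapply(.zoster_strategies, function(s) {
      summarize_trace(run_cohort(params, s, age), params)
    })
    names(res) <- .zoster_strategies
    cmps <- lapply(c("ZVL", "RZV"), function(s) {
      compare_pair(res$NoVaccination, res[[s]], wtp)
    })
    names(cmps) <- c("ZVL", "RZV")
    runs[[as.character(age)]] <- list(
      age = age, results = res, comparisons = cmps,
      frontier = cea_frontier(res, wtp)
    )
  }
  out <- list(ages = ages, wtp = wtp, runs = runs, params = params)
  class(out) <- "zoster_cea"
  out
}

#' Table of base-case results per age and strategy
#'
#' One row per (age, strategy): lifetime HZ and PHN cases, discounted cost
#' and QALYs per 1000 persons, and incremental results versus no vaccination.
#' Reported values follow the reporting convention: ICERs and percentages to
#' the nearest integer (ties away from zero), costs to the nearest USD,
#' QALYs to two decimals; unrounded values are kept in `icer_raw`.
#'
#' @param x A `zoster_cea` object.
#' @param row.names,optional,... Unused, for S3 compatibility.
#' @export
as.data.frame.zoster_cea <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  rows <- list()
  for (run in x$runs) {
    for (s in .zoster_strategies) {
      r <- run$results[[s]]
      cmp <- if (s == "NoVaccination") NULL else run$comparisons[[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        age = run$age,
        strategy = s,
        cases = round_half_away(r$cases_per_1000),
        phn_cases = round_half_away(r$phn_per_1000),
        cost = round_half_away(r$total_cost_per_1000),
        qalys = round_half_away(r$total_qalys_per_1000),
        incr_cost = if (is.null(cmp)) NA_real_ else
          round_half_away(cmp$delta_cost),
        incr_qalys = if (is.null(cmp)) NA_real_ else
          round_half_away(cmp$delta_qaly, 2),
        icer = if (is.null(cmp) || cmp$status != "icer") NA_real_ else
          round_half_away(cmp$icer),
        icer_status = if (is.null(cmp)) "" else cmp$status,
        icer_raw = if (is.null(cmp)) NA_real_ else cmp$icer,
        cost_effective = if (is.null(cmp)) NA else cmp$cost_effective_at_wtp,
        stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s (entry age %d), per 1000 persons:\n",
              x$comparator, x$reference, x$start_age))
  cat(sprintf("  dCost USD %.0f, dQALY %.2f -> %s\n", x$delta_cost,
              x$delta_qaly,
              if (x$status == "icer")
                sprintf("ICER %.0f USD/QALY", x$icer) else x$status))
  cat(sprintf("  NMB at WTP %s: USD %.0f (%scost-effective)\n",
              format(x$wtp, big.mark = ","), x$nmb_at_wtp,
              if (x$cost_effective_at_wtp) "" else "not "))
  invisible(x)
}

#' @export
print.zoster_cea <- function(x, ...) {
  cat("Herpes zoster vaccination cost-effectiveness analysis\n")
  cat(sprintf("  Strategies: %s | WTP: %s USD/QALY | ages: %s\n",
              paste(.zoster_strategies, collapse = ", "),
              format(x$wtp, big.mark = ","),
              paste(x$ages, collapse = ", ")))
  df <- as.data.frame(x)
  print(df[, c("age", "strategy", "cases", "phn_cases", "cost", "qalys",
               "incr_cost", "incr_qalys", "icer")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.zoster_cea <- function(object, ...) {
  df <- as.data.frame(object)
  cat("Incremental analysis versus no vaccination (per 1000 persons)\n")
  for (run in object$runs) {
    for (s in c("ZVL", "RZV")) {
      cmp <- run$comparisons[[s]]
      cases0 <- run$results$NoVaccination$cases_per_1000
      phn0 <- run$results$NoVaccination$phn_per_1000
      av_c <- averted_pct(cases0, run$results[[s]]$cases_per_1000)
      av_p <- averted_pct(phn0, run$results[[s]]$phn_per_1000)
      cat(sprintf(
        "  age %d, %s: averts %d%% of HZ cases, %d%% of PHN; %s; %scost-effective at WTP\n",
        run$age, s, av_c$rounded, av_p$rounded,
        if (cmp$status == "icer") sprintf("ICER %.0f", cmp$icer) else
          cmp$status,
        if (cmp$cost_effective_at_wtp) "" else "not "))
    }
  }
  invisible(df)
}

#' Cost-effectiveness plane for a fitted analysis
#'
#' Plots incremental cost against incremental QALYs (versus no vaccination)
#' for each age and vaccine, with the WTP threshold as a dashed line.
#'
#' @param x A `zoster_cea` object.
#' @param ... Passed to `plot()`.
#' @export
plot.zoster_cea <- function(x, ...) {
  dq <- dc <- numeric(0); lab <- character(0)
  for (run in x$runs) {
    for (s in c("ZVL", "RZV")) {
      dq <- c(dq, run$comparisons[[s]]$delta_qaly)
      dc <- c(dc, run$comparisons[[s]]$delta_cost)
      lab <- c(lab, paste0(s, "@", run$age))
    }
  }
  plot(dq, dc, pch = 19, col = ifelse(grepl("^RZV", lab), 2, 4),
       xlab = "Incremental QALYs per 1000",
       ylab = "Incremental cost (USD per 1000)",
       main = "Cost-effectiveness plane vs no vaccination", ...)
  abline(a = 0, b = x$wtp, lty = 2)
  text(dq, dc, lab, pos = 3, cex = 0.7)
  invisible(x)
}
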