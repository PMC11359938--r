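# Sensitivity analyses: one-way (tornado), probabilistic (PSA + CEAC),
# two-dose compliance scenarios, and the ZVL price threshold.

# ICER of `comparator` vs no vaccination under a parameter set; NA when the
# incremental QALYs are not positive (dominance handled by callers).
.icer_vs_none <- function(params, strategy, start_age) {
  ref <- summarize_trace(run_cohort(params, "NoVaccination", start_age),
                         params)
  cmp <- summarize_trace(run_cohort(params, strategy, start_age), params)
  dc <- cmp$total_cost_per_1000 - ref$total_cost_per_1000
  dq <- cmp$total_qalys_per_1000 - ref$total_qalys_per_1000
  if (dq <= 0) return(NA_real_)
  dc / dq
}

#' One-way (tornado) sensitivity analysis
#'
#' Varies each parameter of `owsa_spec` individually between its lower and
#' upper bound, all else at base case, and records the ICER of the chosen
#' vaccine versus no vaccination at each endpoint. Entries are sorted by bar
#' width (absolute ICER range), the tornado-diagram ordering.
#'
#' @param params A `zoster_params` with nonempty `owsa_spec`.
#' @param strategy Vaccine to compare against no vaccination (`"RZV"` or
#'   `"ZVL"`).
#' @param start_age Vaccination age.
#' @param top_n Number of leading entries to keep (6 by default, the usual
#'   tornado size); `Inf` keeps all.
#' @return An object of class `zoster_tornado`: data.frame with columns
#'   `parameter_path`, `low_value`, `high_value`, `icer_at_low`,
#'   `icer_at_high`, `bar_width`, plus attributes `base_icer`, `strategy`,
#'   `start_age`.
#' @export
one_way_tornado <- function(params, strategy = "RZV", start_age = 60,
                            top_n = 6) {
  strategy <- match.arg(strategy, c("RZV", "ZVL"))
  if (!length(params$owsa_spec)) stop("owsa_spec is empty", call. = FALSE)
  base_icer <- .icer_vs_none(params, strategy, start_age)
  rows <- lapply(params$owsa_spec, function(e) {
    lo <- param_set(params, e$path, e$low)
    hi <- param_set(params, e$path, e$high)
    icer_lo <- .icer_vs_none(lo, strategy, start_age)
    icer_hi <- .icer_vs_none(hi, strategy, start_age)
    data.frame(parameter_path = e$path, low_value = e$low,
               high_value = e$high, icer_at_low = icer_lo,
               icer_at_high = icer_hi,
               bar_width = abs(icer_hi - icer_lo),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$bar_width), , drop = FALSE]
  if (is.finite(top_n)) df <- utils::head(df, top_n)
  rownames(df) <- NULL
  attr(df, "base_icer") <- base_icer
  attr(df, "strategy") <- strategy
  attr(df, "start_age") <- start_age
  class(df) <- c("zoster_tornado", "data.frame")
  df
}

#' @export
print.zoster_tornado <- function(x, ...) {
  cat(sprintf("Tornado: %s vs no vaccination, entry age %d (base ICER %.0f)\n",
              attr(x, "strategy"), attr(x, "start_age"),
              attr(x, "base_icer")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.zoster_tornado <- function(x, ...) {
  n <- nrow(x)
  base <- attr(x, "base_icer")
  lo <- pmin(x$icer_at_low, x$icer_at_high)
  hi <- pmax(x$icer_at_low, x$icer_at_high)
  y <- rev(seq_len(n))
  plot(NA, xlim = range(c(lo, hi, base)), ylim = c(0.5, n + 0.5),
       yaxt = "n", xlab = "ICER (USD/QALY)", ylab = "",
       main = sprintf("One-way sensitivity: %s, age %d",
                      attr(x, "strategy"), attr(x, "start_age")), ...)
  rect(lo, y - 0.35, hi, y + 0.35, col = "grey80")
  abline(v = base, lty = 2)
  axis(2, at = y, labels = x$parameter_path, las = 1, cex.axis = 0.6)
  invisible(x)
}

#' Probabilistic sensitivity analysis with acceptability curves
#'
#' Draws `n_draws` parameter sets from the PSA distributions, runs all three
#' strategies on each draw (common random numbers: the three strategies share
#' every draw, so strategy contrasts are less noisy), and derives the
#' cost-effectiveness acceptability curve: at each willingness-to-pay on the
#' grid, the share of draws in which each strategy attains the maximal net
#' monetary benefit (`wtp * QALY - cost`; ties go to the earlier strategy in
#' the order no-vaccination, ZVL, RZV).
#'
#' @param params A `zoster_params` with nonempty `psa_spec`.
#' @param start_age Vaccination age.
#' @param n_draws Number of Monte Carlo draws (the reference analysis uses
#'   10,000; smaller values are fine for exploration).
#' @param seed Integer seed; a fixed seed makes the run bit-reproducible.
#' @param wtp_grid Willingness-to-pay grid for the CEAC; defaults to 0 to
#'   three times the configured WTP in 101 steps.
#' @return An object of class `zoster_psa`: `draws` (data.frame with one row
#'   per draw and per-strategy cost/QALY columns), `ceac` (long data.frame
#'   `wtp` x `strategy` x `probability`), `n_draws`, `seed`, `start_age`.
#' @export
run_psa <- function(params, start_age = 60, n_draws = 10000, seed = 1,
                    wtp_grid = NULL) {
  if (!length(params$psa_spec)) stop("psa_spec is empty", call. = FALSE)
  if (is.null(wtp_grid)) {
    wtp_grid <- seq(0, 3 * params$economics$wtp, length.out = 101)
  }
  set.seed(seed)
  strategies <- .zoster_strategies
  cost <- matrix(NA_real_, n_draws, 3, dimnames = list(NULL, strategies))
  qaly <- matrix(NA_real_, n_draws, 3, dimnames = list(NULL, strategies))
  for (i in seq_len(n_draws)) {
    draw <- sample_psa_draw(params)
    for (j in seq_along(strategies)) {
      res <- summarize_trace(run_cohort(draw, strategies[j], start_age),
                             draw)
      cost[i, j] <- res$total_cost_per_1000
      qaly[i, j] <- res$total_qalys_per_1000
    }
  }
  ceac <- do.call(rbind, lapply(wtp_grid, function(w) {
    nmb <- w * qaly - cost
    pref <- apply(nmb, 1, which.max)  # ties -> earlier strategy
    data.frame(wtp = w, strategy = strategies,
               probability = as.numeric(tabulate(pref, 3) / n_draws),
               stringsAsFactors = FALSE)
  }))
  draws <- data.frame(draw = seq_len(n_draws), cost, qaly)
  names(draws) <- c("draw", paste0("cost_", strategies),
                    paste0("qaly_", strategies))
  out <- list(draws = draws, ceac = ceac, n_draws = n_draws, seed = seed,
              start_age = start_age, wtp_grid = wtp_grid)
  class(out) <- "zoster_psa"
  out
}

#' Probability each strategy is preferred at a willingness-to-pay
#'
#' @param psa A `zoster_psa` object.
#' @param wtp Willingness-to-pay threshold, USD per QALY.
#' @return Named numeric vector of preference probabilities (sums to 1).
#' @export
psa_preference <- function(psa, wtp) {
  strategies <- .zoster_strategies
  cost <- as.matrix(psa$draws[, paste0("cost_", strategies)])
  qaly <- as.matrix(psa$draws[, paste0("qaly_", strategies)])
  nmb <- wtp * qaly - cost
  pref <- apply(nmb, 1, which.max)
  stats::setNames(as.numeric(tabulate(pref, 3) / psa$n_draws), strategies)
}

#' @export
print.zoster_psa <- function(x, ...) {
  cat(sprintf("PSA: %d draws, entry age %d, seed %d\n", x$n_draws,
              x$start_age, x$seed))
  w <- x$wtp_grid[ceiling(length(x$wtp_grid) / 3)]
  p <- psa_preference(x, w)
  cat(sprintf("  Preference at WTP %.0f: %s\n", w,
              paste(sprintf("%s %.1f%%", names(p), 100 * p),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.zoster_psa <- function(x, ...) {
  strategies <- .zoster_strategies
  wtp <- sort(unique(x$ceac$wtp))
  mat <- sapply(strategies, function(s) {
    x$ceac$probability[x$ceac$strategy == s][order(x$ceac$wtp[
      x$ceac$strategy == s])]
  })
  matplot(wtp, mat, type = "l", lty = 1, lwd = 2, col = c(1, 4, 2),
          xlab = "Willingness-to-pay (USD/QALY)",
          ylab = "Probability cost-effective",
          main = "Cost-effectiveness acceptability curves", ...)
  legend("right", legend = strategies, col = c(1, 4, 2), lwd = 2, bty = "n")
  invisible(x)
}

#' Two-dose compliance scenario sweep
#'
#' Recomputes the RZV-versus-no-vaccination ICER for a range of two-dose
#' completion rates. Dose costs follow compliance (completers pay two doses,
#' non-completers one) and cohort efficacy is the compliance-weighted mixture
#' of the two-dose and one-dose waning curves.
#'
#' @param params A `zoster_params`.
#' @param rates Two-dose completion fractions to evaluate (0.2 to 1 by 0.2
#'   by default, the usual scenario grid).
#' @param ages Vaccination ages.
#' @return Data.frame with columns `age`, `compliance`, `icer`,
#'   `cost_effective` (at the configured WTP).
#' @export
compliance_scenario <- function(params, rates = seq(0.2, 1, by = 0.2),
                                ages = c(50, 60, 70, 80)) {
  if (any(rates < 0 | rates > 1)) {
    stop("compliance rates must be in [0, 1]", call. = FALSE)
  }
  wtp <- params$economics$wtp
  rows <- list()
  for (age in ages) {
    for (rate in rates) {
      p <- param_set(params, "economics.compliance_two_dose", rate)
      icer <- .icer_vs_none(p, "RZV", age)
      rows[[length(rows) + 1L]] <- data.frame(
        age = age, compliance = rate, icer = icer,
        cost_effective = !is.na(icer) && icer < wtp,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' ZVL price threshold analysis
#'
#' Finds the per-dose price of the live attenuated vaccine at which its net
#' monetary benefit equals that of the recombinant vaccine at the configured
#' willingness-to-pay — i.e. the price below which ZVL gains the
#' cost-effectiveness advantage. NMB is affine in the dose price (the dose is
#' charged once, undiscounted, at cycle 0), so the crossing is solved in
#' closed form from two model evaluations.
#'
#' @param params A `zoster_params`; RZV must have the higher NMB at the base
#'   price (it does in the base case).
#' @param start_age Vaccination age.
#' @return An object of class `threshold_result`: list with `age_band`,
#'   `start_age`, `threshold_price` (USD per ZVL dose),
#'   `pct_reduction_from_base`, `base_price`, and `status`
#'   (`"ok"` or `"not achievable by price alone"` when no crossing exists at
#'   a nonnegative price).
#' @export
zvl_price_threshold <- function(params, start_age = 60) {
  wtp <- params$economics$wtp
  nmb_of <- function(p) {
    res_r <- summarize_trace(run_cohort(p, "RZV", start_age), p)
    res_z <- summarize_trace(run_cohort(p, "ZVL", start_age), p)
    c(zvl = wtp * res_z$total_qalys_per_1000 - res_z$total_cost_per_1000,
      rzv = wtp * res_r$total_qalys_per_1000 - res_r$total_cost_per_1000)
  }
  base_price <- params$costs$price_zvl_dose
  nmb_base <- nmb_of(params)
  if (nmb_base["zvl"] >= nmb_base["rzv"]) {
    stop("precondition failed: RZV must have higher NMB than ZVL at the ",
         "base price", call. = FALSE)
  }
  nmb_zero <- nmb_of(param_set(params, "costs.price_zvl_dose", 0))
  # NMB_ZVL(price) is affine with slope derived from the two evaluations;
  # NMB_RZV does not depend on the ZVL price.
  slope <- (nmb_base["zvl"] - nmb_zero["zvl"]) / base_price
  p_star <- unname((nmb_base["rzv"] - nmb_zero["zvl"]) / slope)
  status <- "ok"
  if (p_star < 0 || p_star > base_price) {
    status <- "not achievable by price alone"
    p_star <- NA_real_
  }
  out <- list(
    age_band = band_of(start_age), start_age = start_age,
    threshold_price = p_star,
    pct_reduction_from_base = if (is.na(p_star)) NA_real_ else
      100 * (base_price - p_star) / base_price,
    base_price = base_price, status = status
  )
  class(out) <- "threshold_result"
  out
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("ZVL price threshold, entry age %d (band %s):\n", x$start_age,
              x$age_band))
  if (x$status == "ok") {
    cat(sprintf("  ZVL matches RZV's NMB at USD %.1f per dose (a %.1f%% reduction from %.2f)\n",
                x$threshold_price, x$pct_reduction_from_base, x$base_price))
  } else {
    cat("  ", x$status, "\n", sep = "")
  }
  invisible(x)
}
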