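# Vaccine efficacy as a linear function of years since vaccination, fitted to
# trial follow-up anchors and clamped to [0, 1] on evaluation. Beyond the last
# anchor the fitted line is extrapolated until it reaches 0 and held there
# (the clamp implements both the floor and the no-rebound rule).

#' Fit a linear waning curve through efficacy anchors
#'
#' Ordinary least squares through `(years since vaccination, efficacy)`
#' anchors. With exactly two anchors this is the line through the two points.
#'
#' @param anchors Either a two-column matrix/data.frame `(years, ve)` or a
#'   list with elements `years` and `ve`. At least two distinct time points
#'   are required; efficacies must lie in [0, 1] and years must be
#'   nonnegative.
#' @param vaccine,band Optional labels stored on the curve.
#' @return An object of class `efficacy_curve` with fields `intercept`,
#'   `slope`, `max_followup`, `vaccine`, `band`.
#' @examples
#' cv <- fit_linear_waning(cbind(c(0, 10), c(0.70, 0.20)))
#' coef(cv)                      # intercept 0.70, slope -0.05
#' predict(cv, years = c(0, 20)) # 0.70, then clamped to 0
#' @export
fit_linear_waning <- function(anchors, vaccine = NA_character_,
                              band = NA_character_) {
  if (is.list(anchors) && !is.data.frame(anchors) &&
      all(c("years", "ve") %in% names(anchors))) {
    years <- as.numeric(anchors$years)
    ve <- as.numeric(anchors$ve)
  } else {
    m <- as.matrix(anchors)
    years <- as.numeric(m[, 1])
    ve <- as.numeric(m[, 2])
  }
  if (length(unique(years)) < 2L) {
    stop("need at least 2 distinct time points to fit a waning line",
         call. = FALSE)
  }
  if (any(years < 0)) stop("anchor years must be >= 0", call. = FALSE)
  if (any(ve < 0 | ve > 1)) {
    stop("anchor efficacies must be in [0, 1]", call. = FALSE)
  }
  fit <- stats::lm(ve ~ years)
  out <- list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    max_followup = max(years),
    vaccine = vaccine,
    band = band
  )
  class(out) <- "efficacy_curve"
  out
}

#' Evaluate vaccine efficacy at a time since vaccination
#'
#' Linear prediction `intercept + slope * years`, clamped to [0, 1]. The
#' resulting efficacy multiplies `(1 - VE)` onto the unvaccinated herpes
#' zoster incidence in the cohort engine.
#'
#' @param curve An `efficacy_curve`.
#' @param years Nonnegative numeric vector of years since vaccination.
#' @return Efficacy fraction(s) in [0, 1].
#' @export
efficacy_at <- function(curve, years) {
  stopifnot(inherits(curve, "efficacy_curve"))
  if (any(years < 0)) stop("years since vaccination must be >= 0",
                           call. = FALSE)
  pmin(pmax(curve$intercept + curve$slope * years, 0), 1)
}

#' Effective RZV efficacy under partial two-dose compliance
#'
#' The recombinant vaccine schedule is two doses; recipients who stop after
#' the first dose are assumed to retain a reduced protection curve. The
#' cohort-level efficacy is the compliance-weighted mixture of the two curves.
#'
#' @param curve_two_dose,curve_one_dose `efficacy_curve` objects.
#' @param compliance_two_dose Fraction of recipients completing both doses.
#' @param years Years since vaccination.
#' @return Efficacy fraction(s) in [0, 1].
#' @export
effective_rzv_efficacy <- function(curve_two_dose, curve_one_dose,
                                   compliance_two_dose, years) {
  if (compliance_two_dose < 0 || compliance_two_dose > 1) {
    stop("compliance must be in [0, 1]", call. = FALSE)
  }
  compliance_two_dose * efficacy_at(curve_two_dose, years) +
    (1 - compliance_two_dose) * efficacy_at(curve_one_dose, years)
}

# Curves for one strategy and vaccination-age band, built from the anchors in
# the parameter set. RZV one-dose protection defaults to the two-dose curve
# scaled by `rzv_one_dose_factor` (a stated modelling assumption; the single
# published anchor structure does not cover one-dose recipients).
.strategy_curves <- function(params, strategy, start_age) {
  b <- band_of(start_age)
  if (strategy == "NoVaccination") return(NULL)
  if (strategy == "ZVL") {
    return(list(main = fit_linear_waning(params$efficacy$anchors$ZVL[[b]],
                                         vaccine = "ZVL", band = b)))
  }
  two <- fit_linear_waning(params$efficacy$anchors$RZV[[b]],
                           vaccine = "RZV", band = b)
  one <- two
  f <- params$efficacy$rzv_one_dose_factor
  one$intercept <- two$intercept * f
  one$slope <- two$slope * f
  list(main = two, one_dose = one)
}

# Strategy-level VE at cycle t (vectorized over t).
.strategy_ve <- function(params, strategy, curves, t) {
  if (strategy == "NoVaccination" || is.null(curves)) return(rep(0, length(t)))
  if (strategy == "ZVL") return(efficacy_at(curves$main, t))
  effective_rzv_efficacy(curves$main, curves$one_dose,
                         params$economics$compliance_two_dose, t)
}

#' @export
coef.efficacy_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @param newdata,years Years since vaccination at which to evaluate; `years`
#'   is accepted as an alias.
#' @rdname efficacy_at
#' @export
predict.efficacy_curve <- function(object, newdata = NULL, years = NULL, ...) {
  t <- years %||% newdata
  if (is.null(t)) t <- seq(0, object$max_followup)
  efficacy_at(object, t)
}

#' @export
print.efficacy_curve <- function(x, ...) {
  lab <- paste(stats::na.omit(c(x$vaccine, x$band)), collapse = ", ")
  cat("Linear vaccine efficacy waning curve",
      if (nzchar(lab)) paste0(" (", lab, ")"), "\n", sep = "")
  cat(sprintf("  VE(t) = clamp(%.4f %+.4f t, 0, 1); anchors span %.1f years\n",
              x$intercept, x$slope, x$max_followup))
  invisible(x)
}
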