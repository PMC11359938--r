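# Synthetic but structurally valid parameter sets, and probabilistic
# sensitivity draws. Distribution families follow standard health-economics
# practice: beta for probabilities/utilities/efficacies, gamma for costs,
# uniform between one-way bounds when nothing else is known. Hyperparameters
# are derived by method of moments from (base, low, high), treating
# (high - low) / (2 * 1.96) as a standard error.

#' Generate a random, structurally valid parameter set
#'
#' Produces a complete `zoster_params` that passes `validate_parameters()`,
#' for testing every downstream stage without real source data. With
#' `difficulty = "realistic"` the magnitudes bracket published values:
#' incidence and conditional PHN probability rise with age band, costs are
#' positive and right-skewed, efficacy anchors wane over follow-up, and the
#' life table rises roughly geometrically with age. `"easy"` draws smoother,
#' lower-variance inputs useful for numerical oracles.
#'
#' @param seed Integer seed; the same seed always yields the same set.
#' @param difficulty `"easy"` or `"realistic"`.
#' @return A validated `zoster_params` object (with PSA and one-way
#'   specifications attached).
#' @examples
#' p <- make_synthetic_parameters(1)
#' nrow(validate_parameters(p))  # 0
#' @export
make_synthetic_parameters <- function(seed, difficulty = c("realistic",
                                                           "easy")) {
  difficulty <- match.arg(difficulty)
  params <- default_parameters()
  set.seed(seed)
  bands <- age_bands()$label
  jitter_frac <- if (difficulty == "easy") 0.05 else 0.25

  rise <- function(base, lo_mult = 0.6, hi_mult = 1.6) {
    # monotone non-decreasing across the four bands, jittered around base
    raw <- base * sort(stats::runif(4, lo_mult, hi_mult))
    stats::setNames(raw, bands)
  }
  epi <- params$epidemiology
  epi$hz_incidence <- rise(stats::runif(1, 0.004, 0.010))
  epi$p_phn_given_hz <- pmin(rise(stats::runif(1, 0.10, 0.30)), 0.9)
  epi$p_other_comp_given_hz <-
    stats::setNames(stats::runif(4, 0.01, 0.06), bands)
  epi$hz_case_fatality <-
    stats::setNames(sort(stats::runif(4, 1e-5, 3e-3)), bands)
  epi$p_recurrence <- stats::runif(1, 0.002, 0.02)
  ages <- 50:100
  q50 <- stats::runif(1, 0.002, 0.005)
  growth <- stats::runif(1, 0.07, 0.10)
  epi$all_cause_mortality <-
    stats::setNames(pmin(q50 * exp(growth * (ages - 50)), 0.9), ages)
  params$epidemiology <- epi

  cc <- params$costs
  for (f in c("cost_hz_episode", "cost_phn", "cost_other_comp",
              "cost_nonmedical", "cost_indirect")) {
    # lognormal jitter: positive and right-skewed
    cc[[f]] <- cc[[f]] * stats::rlnorm(1, 0, jitter_frac)
  }
  params$costs <- cc

  uu <- params$utilities
  u50 <- stats::runif(1, 0.87, 0.95)
  uu$u_healthy <- stats::setNames(
    pmax(u50 - stats::runif(1, 0.001, 0.004) * (ages - 50), 0.5), ages)
  uu$u_hz <- stats::runif(1, 0.78, min(0.9, u50))
  uu$u_phn <- stats::runif(1, 0.6, uu$u_hz)
  uu$u_other_comp <- stats::runif(1, 0.6, uu$u_hz)
  params$utilities <- uu

  anchors <- params$efficacy$anchors
  for (vac in names(anchors)) {
    hi <- if (vac == "RZV") c(0.90, 0.99) else c(0.15, 0.75)
    for (b in bands) {
      t_end <- anchors[[vac]][[b]]$years[2]
      ve0 <- stats::runif(1, hi[1], hi[2])
      ve_end <- stats::runif(1, 0, ve0)
      anchors[[vac]][[b]] <- list(years = c(0, t_end), ve = c(ve0, ve_end))
    }
  }
  params$efficacy$anchors <- anchors

  viol <- validate_parameters(params)
  if (nrow(viol)) {
    stop("internal error: synthetic parameter set failed validation",
         call. = FALSE)
  }
  params
}

# One draw from a PSA entry given the base value. Families: beta on [0,1]
# quantities, gamma/lognormal on nonnegative ones, uniform between bounds,
# point = no uncertainty. Explicit hyperparameters in the entry win over
# moment matching from (base, low, high).
.psa_draw_one <- function(entry, base) {
  fam <- entry$family
  if (fam == "point") return(base)
  if (fam == "uniform") {
    return(stats::runif(1, entry$low, entry$high))
  }
  se <- if (!is.null(entry$sd)) entry$sd else (entry$high - entry$low) /
    (2 * 1.96)
  if (se <= 0) return(base)
  v <- se^2
  if (fam == "beta") {
    if (base <= 0 || base >= 1) {
      stop("beta family needs a base value strictly inside (0, 1) for `",
           entry$path, "`", call. = FALSE)
    }
    if (!is.null(entry$shape1)) {
      return(stats::rbeta(1, entry$shape1, entry$shape2))
    }
    nu <- base * (1 - base) / v - 1
    if (nu <= 0) {
      stop("beta variance too large for mean of `", entry$path, "`",
           call. = FALSE)
    }
    return(stats::rbeta(1, base * nu, (1 - base) * nu))
  }
  if (fam == "gamma") {
    if (base <= 0) {
      stop("gamma family needs a positive base value for `", entry$path, "`",
           call. = FALSE)
    }
    if (!is.null(entry$shape)) {
      return(stats::rgamma(1, shape = entry$shape, rate = entry$rate))
    }
    return(stats::rgamma(1, shape = base^2 / v, rate = base / v))
  }
  if (fam == "lognormal") {
    if (base <= 0) {
      stop("lognormal family needs a positive base value for `", entry$path,
           "`", call. = FALSE)
    }
    if (!is.null(entry$meanlog)) {
      return(stats::rlnorm(1, entry$meanlog, entry$sdlog))
    }
    s2 <- log(1 + v / base^2)
    return(stats::rlnorm(1, log(base) - s2 / 2, sqrt(s2)))
  }
  stop("unknown PSA family: ", fam, call. = FALSE)
}

#' Draw one probabilistic-sensitivity parameter set
#'
#' Replaces every target of the parameter set's `psa_spec` with one random
#' draw from its distribution, leaving all other inputs untouched. Draws are
#' taken in sorted order of the dotted target paths from the current RNG
#' stream, so a run seeded once is bit-reproducible. If a drawn set violates
#' any structural invariant (e.g. a utility ordering), the whole set is
#' redrawn — rejection rather than clipping, to avoid probability mass at the
#' bounds — up to 1000 times.
#'
#' @param params A `zoster_params` with a nonempty `psa_spec`.
#' @return A new, validated `zoster_params`.
#' @examples
#' p <- default_parameters()
#' set.seed(1)
#' draw <- sample_psa_draw(p)
#' @export
sample_psa_draw <- function(params) {
  spec <- params$psa_spec
  if (!length(spec)) stop("psa_spec is empty", call. = FALSE)
  paths <- vapply(spec, `[[`, "", "path")
  spec <- spec[order(paths)]
  for (try in seq_len(1000L)) {
    out <- params
    for (e in spec) {
      base <- param_get(params, e$path)
      out <- param_set(out, e$path, .psa_draw_one(e, base))
    }
    if (!nrow(validate_parameters(out))) return(out)
  }
  stop("could not draw a valid parameter set in 1000 tries; ",
       "check psa_spec ranges", call. = FALSE)
}
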