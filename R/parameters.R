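# Parameter container: load, validate, address by dotted path, serialize.
#
# A `zoster_params` object is a nested list with sections
#   epidemiology / costs / utilities / economics / efficacy / model /
#   psa_spec / owsa_spec
# Band-indexed inputs are named numeric vectors keyed by band label; the life
# table and background utilities are named numeric vectors keyed by single
# year of age. All monetary values are 2023 USD internally; configs may be
# written in CNY and are converted once at load.

.param_schema <- list(
  epidemiology = c("hz_incidence", "p_phn_given_hz", "p_other_comp_given_hz",
                   "hz_case_fatality", "p_recurrence", "all_cause_mortality"),
  costs = c("cost_hz_episode", "cost_phn", "cost_other_comp",
            "cost_nonmedical", "cost_indirect", "price_rzv_dose",
            "price_zvl_dose", "cost_admin_dose", "cny_per_usd"),
  utilities = c("u_healthy", "u_hz", "u_phn", "u_other_comp", "u_dead"),
  economics = c("discount_rate", "horizon", "wtp", "coverage",
                "compliance_two_dose"),
  efficacy = c("anchors", "rzv_one_dose_factor", "phn_multiplier"),
  model = c("half_cycle_correction", "phn_exit_prob", "comp_exit_prob",
            "vaccine_disutility", "vaccine_ae_cost")
)

.cost_fields <- c("cost_hz_episode", "cost_phn", "cost_other_comp",
                  "cost_nonmedical", "cost_indirect", "price_rzv_dose",
                  "price_zvl_dose", "cost_admin_dose")

#' Load a model parameterization from a config file
#'
#' Reads a YAML (or JSON) configuration describing every input of the cohort
#' model, applies optional dotted-path overrides, converts CNY costs to USD
#' when the config declares `currency: CNY`, and validates the result.
#' Unknown keys anywhere in the config are rejected.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @param overrides Optional named list (or named vector) of dotted-path
#'   overrides, e.g. `list("economics.discount_rate" = 0)`. Overrides are
#'   applied after the file values and before validation.
#' @return A validated `zoster_params` object.
#' @seealso [default_parameters()], [validate_parameters()], [param_get()]
#' @examples
#' p <- default_parameters()
#' p0 <- default_parameters(overrides = list("economics.discount_rate" = 0))
#' p0$economics$discount_rate
#' @export
load_parameters <- function(path, overrides = NULL) {
  if (!file.exists(path)) {
    stop("parameter config not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  params <- .as_param_set(raw)
  if (!is.null(overrides) && length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("`overrides` must be a fully named list of dotted paths",
           call. = FALSE)
    }
    for (key in names(overrides)) {
      params <- param_set(params, key, overrides[[key]])
    }
  }
  viol <- validate_parameters(params)
  if (nrow(viol)) {
    stop("invalid parameter set:\n",
         paste0("  - ", viol$field, " = ", viol$value, ": ", viol$rule,
                collapse = "\n"),
         call. = FALSE)
  }
  params
}

#' Packaged base-case parameterization
#'
#' Loads the default configuration shipped with the package
#' (`basecase.yaml`). Prices, administration cost, utilities for acute zoster
#' and postherpetic neuralgia, discount rate, horizon, willingness-to-pay and
#' the initial efficacy anchors are the published point values; the remaining
#' inputs (age-specific incidence, conditional complication probabilities,
#' life table, disease costs, background utilities, sensitivity ranges) are
#' literature-plausible placeholders that a user should replace with their own
#' source data for a substantive analysis. See the package vignette.
#'
#' @inheritParams load_parameters
#' @return A validated `zoster_params` object.
#' @export
default_parameters <- function(overrides = NULL) {
  path <- system.file("extdata", "basecase.yaml", package = "zostercea",
                      mustWork = TRUE)
  load_parameters(path, overrides = overrides)
}

# Coerce the raw parsed config into the canonical internal representation,
# rejecting unknown keys and converting currency.
.as_param_set <- function(raw) {
  if (!is.list(raw)) stop("config must be a mapping", call. = FALSE)
  currency <- raw[["currency"]]
  raw[["currency"]] <- NULL
  known_top <- c(names(.param_schema), "psa_spec", "owsa_spec")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_top <- setdiff(names(.param_schema), names(raw))
  if (length(missing_top)) {
    stop("missing required config section(s): ",
         paste(missing_top, collapse = ", "), call. = FALSE)
  }
  for (section in names(.param_schema)) {
    sec <- raw[[section]]
    if (!is.list(sec)) stop("section `", section, "` must be a mapping",
                            call. = FALSE)
    unknown <- setdiff(names(sec), .param_schema[[section]])
    if (length(unknown)) {
      stop("unknown key(s) in `", section, "`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    missing <- setdiff(.param_schema[[section]], names(sec))
    if (length(missing)) {
      stop("missing required field(s) in `", section, "`: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }

  bands <- age_bands()$label
  as_band_vec <- function(x, what) {
    v <- unlist(x)
    missing <- setdiff(bands, names(v))
    if (length(missing)) {
      stop("`", what, "` is missing band(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(names(v), bands)
    if (length(extra)) {
      stop("`", what, "` has unknown band(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    as.numeric(v[bands]) -> out
    names(out) <- bands
    out
  }
  as_age_vec <- function(x, what) {
    v <- unlist(x)
    ages <- suppressWarnings(as.integer(names(v)))
    if (any(is.na(ages))) {
      stop("`", what, "` must be keyed by integer age", call. = FALSE)
    }
    out <- as.numeric(v[order(ages)])
    names(out) <- sort(ages)
    out
  }

  epi <- raw$epidemiology
  epi$hz_incidence <- as_band_vec(epi$hz_incidence, "hz_incidence")
  epi$p_phn_given_hz <- as_band_vec(epi$p_phn_given_hz, "p_phn_given_hz")
  epi$p_other_comp_given_hz <-
    as_band_vec(epi$p_other_comp_given_hz, "p_other_comp_given_hz")
  epi$hz_case_fatality <- as_band_vec(epi$hz_case_fatality, "hz_case_fatality")
  epi$p_recurrence <- as.numeric(epi$p_recurrence)
  epi$all_cause_mortality <-
    as_age_vec(epi$all_cause_mortality, "all_cause_mortality")

  util <- raw$utilities
  util$u_healthy <- as_age_vec(util$u_healthy, "u_healthy")
  for (f in c("u_hz", "u_phn", "u_other_comp", "u_dead")) {
    util[[f]] <- as.numeric(util[[f]])
  }

  costs <- lapply(raw$costs, as.numeric)
  if (!is.null(currency)) {
    if (!currency %in% c("USD", "CNY")) {
      stop("`currency` must be USD or CNY", call. = FALSE)
    }
    if (identical(currency, "CNY")) {
      fx <- costs$cny_per_usd
      for (f in .cost_fields) costs[[f]] <- costs[[f]] / fx
    }
  }

  econ <- lapply(raw$economics, as.numeric)
  econ$horizon <- as.integer(econ$horizon)

  eff <- raw$efficacy
  eff$rzv_one_dose_factor <- as.numeric(eff$rzv_one_dose_factor)
  eff$phn_multiplier <- lapply(eff$phn_multiplier, as.numeric)
  anchors <- eff$anchors
  for (vac in names(anchors)) {
    if (!vac %in% c("RZV", "ZVL")) {
      stop("unknown vaccine in efficacy anchors: ", vac, call. = FALSE)
    }
    missing <- setdiff(bands, names(anchors[[vac]]))
    if (length(missing)) {
      stop("efficacy anchors for ", vac, " missing band(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (b in bands) {
      a <- anchors[[vac]][[b]]
      # accept either {years: [...], ve: [...]} or a list of [year, ve] pairs
      if (!is.null(a$years)) {
        anchors[[vac]][[b]] <- list(years = as.numeric(unlist(a$years)),
                                    ve = as.numeric(unlist(a$ve)))
      } else {
        m <- do.call(rbind, lapply(a, as.numeric))
        anchors[[vac]][[b]] <- list(years = m[, 1], ve = m[, 2])
      }
    }
    anchors[[vac]] <- anchors[[vac]][bands]
  }
  eff$anchors <- anchors[c("RZV", "ZVL")]

  model <- raw$model
  model$half_cycle_correction <- isTRUE(model$half_cycle_correction)
  for (f in c("phn_exit_prob", "comp_exit_prob", "vaccine_disutility",
              "vaccine_ae_cost")) {
    model[[f]] <- as.numeric(model[[f]])
  }

  norm_spec <- function(spec) {
    lapply(spec, function(e) {
      e$path <- as.character(e$path)
      for (f in setdiff(names(e), c("path", "family"))) {
        e[[f]] <- as.numeric(e[[f]])
      }
      e
    })
  }

  params <- list(
    epidemiology = epi[.param_schema$epidemiology],
    costs = costs[.param_schema$costs],
    utilities = util[.param_schema$utilities],
    economics = econ[.param_schema$economics],
    efficacy = eff[.param_schema$efficacy],
    model = model[.param_schema$model],
    psa_spec = norm_spec(raw$psa_spec),
    owsa_spec = norm_spec(raw$owsa_spec)
  )
  class(params) <- "zoster_params"
  params
}

#' Read a scalar model input by dotted path
#'
#' Dotted paths address the nested parameter structure, e.g.
#' `"costs.price_rzv_dose"`, `"epidemiology.hz_incidence.60-69"` or
#' `"efficacy.anchors.RZV.50-59.ve.1"` (1-based index into the anchor vector).
#'
#' @param params A `zoster_params` object.
#' @param path Dotted path string.
#' @return The addressed value.
#' @export
param_get <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params
  for (k in keys) {
    idx <- if (!is.null(names(node)) && k %in% names(node)) {
      k
    } else if (grepl("^[0-9]+$", k) && as.integer(k) <= length(node)) {
      as.integer(k)
    } else {
      stop("parameter path not found: ", path, " (at `", k, "`)",
           call. = FALSE)
    }
    node <- node[[idx]]
  }
  node
}

#' Set a scalar model input by dotted path
#'
#' @inheritParams param_get
#' @param value Replacement value.
#' @return The modified `zoster_params` object.
#' @export
param_set <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  set_rec <- function(node, keys, value) {
    k <- keys[[1]]
    idx <- if (!is.null(names(node)) && k %in% names(node)) {
      k
    } else if (grepl("^[0-9]+$", k) && as.integer(k) <= length(node)) {
      as.integer(k)
    } else {
      stop("parameter path not found (at `", k, "`)", call. = FALSE)
    }
    if (length(keys) == 1L) {
      node[[idx]] <- value
    } else {
      node[[idx]] <- set_rec(node[[idx]], keys[-1], value)
    }
    node
  }
  out <- tryCatch(set_rec(unclass(params), keys, value),
                  error = function(e) {
                    stop("parameter path not found: ", path, call. = FALSE)
                  })
  class(out) <- "zoster_params"
  out
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model inputs: probabilities and
#' utilities on [0, 1], nonnegative costs, a positive willingness-to-pay,
#' an integer horizon of at least one cycle, utility ordering
#' (`u_phn <= u_hz <= max(u_healthy)`, `u_dead == 0`), at least two efficacy
#' anchors per curve, and that every path referenced by the sensitivity
#' specifications exists. Violations are returned, not raised, so the function
#' is usable as a filter; `load_parameters()` raises on any violation.
#'
#' @param params A `zoster_params` object (possibly invalid).
#' @return A data.frame with columns `field`, `value`, `rule`; zero rows iff
#'   the parameter set is valid.
#' @examples
#' nrow(validate_parameters(default_parameters()))  # 0
#' @export
validate_parameters <- function(params) {
  v <- list()
  add <- function(field, value, rule) {
    v[[length(v) + 1L]] <<- data.frame(
      field = field, value = paste(format(value), collapse = ","),
      rule = rule, stringsAsFactors = FALSE)
  }
  check_prob <- function(x, field) {
    bad <- !is.finite(x) | x < 0 | x > 1
    if (any(bad)) {
      lab <- if (!is.null(names(x))) names(x)[bad] else seq_along(x)[bad]
      for (i in which(bad)) {
        add(paste0(field, if (length(x) > 1)
          paste0(".", names(x)[i] %||% i) else ""), x[i], "must be in [0, 1]")
      }
    }
  }
  epi <- params$epidemiology
  check_prob(epi$hz_incidence, "epidemiology.hz_incidence")
  check_prob(epi$p_phn_given_hz, "epidemiology.p_phn_given_hz")
  check_prob(epi$p_other_comp_given_hz, "epidemiology.p_other_comp_given_hz")
  check_prob(epi$hz_case_fatality, "epidemiology.hz_case_fatality")
  check_prob(epi$p_recurrence, "epidemiology.p_recurrence")
  check_prob(epi$all_cause_mortality, "epidemiology.all_cause_mortality")

  for (f in .cost_fields) {
    x <- params$costs[[f]]
    if (!is.finite(x) || x < 0) add(paste0("costs.", f), x, "must be >= 0")
  }
  if (!is.finite(params$costs$cny_per_usd) || params$costs$cny_per_usd <= 0) {
    add("costs.cny_per_usd", params$costs$cny_per_usd, "must be > 0")
  }

  util <- params$utilities
  check_prob(util$u_healthy, "utilities.u_healthy")
  check_prob(util$u_hz, "utilities.u_hz")
  check_prob(util$u_phn, "utilities.u_phn")
  check_prob(util$u_other_comp, "utilities.u_other_comp")
  if (!identical(as.numeric(util$u_dead), 0)) {
    add("utilities.u_dead", util$u_dead, "must be 0")
  }
  if (is.finite(util$u_phn) && is.finite(util$u_hz) &&
      util$u_phn > util$u_hz) {
    add("utilities.u_phn", util$u_phn, "must be <= u_hz")
  }
  if (is.finite(util$u_hz) && length(util$u_healthy) &&
      util$u_hz > max(util$u_healthy)) {
    add("utilities.u_hz", util$u_hz, "must be <= max(u_healthy)")
  }

  econ <- params$economics
  if (!is.finite(econ$discount_rate) || econ$discount_rate < 0) {
    add("economics.discount_rate", econ$discount_rate, "must be >= 0")
  }
  if (is.na(econ$horizon) || econ$horizon < 1L) {
    add("economics.horizon", econ$horizon, "must be an integer >= 1")
  }
  if (!is.finite(econ$wtp) || econ$wtp <= 0) {
    add("economics.wtp", econ$wtp, "must be > 0")
  }
  check_prob(econ$coverage, "economics.coverage")
  check_prob(econ$compliance_two_dose, "economics.compliance_two_dose")

  eff <- params$efficacy
  if (!is.finite(eff$rzv_one_dose_factor) || eff$rzv_one_dose_factor < 0 ||
      eff$rzv_one_dose_factor > 1) {
    add("efficacy.rzv_one_dose_factor", eff$rzv_one_dose_factor,
        "must be in [0, 1]")
  }
  for (vac in names(eff$anchors)) {
    for (b in names(eff$anchors[[vac]])) {
      a <- eff$anchors[[vac]][[b]]
      fld <- paste0("efficacy.anchors.", vac, ".", b)
      if (length(unique(a$years)) < 2L) {
        add(fld, a$years, "needs >= 2 distinct time points")
      }
      if (any(a$years < 0)) add(fld, a$years, "years must be >= 0")
      check_prob(a$ve, paste0(fld, ".ve"))
    }
  }
  for (vac in names(eff$phn_multiplier)) {
    x <- eff$phn_multiplier[[vac]]
    if (!is.finite(x) || x < 0) {
      add(paste0("efficacy.phn_multiplier.", vac), x, "must be >= 0")
    }
  }

  mod <- params$model
  check_prob(mod$phn_exit_prob, "model.phn_exit_prob")
  check_prob(mod$comp_exit_prob, "model.comp_exit_prob")

  for (spec_name in c("psa_spec", "owsa_spec")) {
    for (e in params[[spec_name]]) {
      ok <- tryCatch({
        val <- param_get(params, e$path)
        is.numeric(val) && length(val) == 1L
      }, error = function(err) FALSE)
      if (!ok) {
        add(paste0(spec_name, ".", e$path), e$path,
            "must address an existing scalar parameter")
      }
    }
  }
  fam_ok <- c("beta", "gamma", "lognormal", "uniform", "point")
  for (e in params$psa_spec) {
    if (!e$family %in% fam_ok) {
      add(paste0("psa_spec.", e$path), e$family,
          paste("family must be one of", paste(fam_ok, collapse = "/")))
    }
  }

  if (length(v)) do.call(rbind, v) else {
    data.frame(field = character(), value = character(), rule = character(),
               stringsAsFactors = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a parameter set to YAML
#'
#' Writes a config file that [load_parameters()] reads back to an identical
#' parameter set (round-trip property).
#'
#' @param params A `zoster_params` object.
#' @param path Output file path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  as_map <- function(x) as.list(x)  # named numeric vector -> YAML mapping
  out <- unclass(params)
  out$epidemiology <- lapply(out$epidemiology, function(x) {
    if (is.numeric(x) && length(x) > 1) as_map(x) else x
  })
  out$utilities <- lapply(out$utilities, function(x) {
    if (is.numeric(x) && length(x) > 1) as_map(x) else x
  })
  yaml::write_yaml(out, path, precision = 12L)
  invisible(path)
}

#' Read band- or age-indexed values from a two-column CSV
#'
#' Accepts a header row of either `band_label,value` or `age,value` and
#' returns a named numeric vector suitable for use as an override, e.g.
#' `list("epidemiology.hz_incidence" = read_param_csv(f))`.
#'
#' @param path CSV file path.
#' @return Named numeric vector keyed by band label or age.
#' @export
read_param_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) != 2L) stop("expected a two-column CSV", call. = FALSE)
  key <- names(df)[1]
  if (!key %in% c("band_label", "age")) {
    stop("first column must be `band_label` or `age`", call. = FALSE)
  }
  out <- as.numeric(df[[2]])
  names(out) <- as.character(df[[1]])
  out
}

# Age-table lookup: ages outside the tabulated range use the nearest entry.
.age_lookup <- function(tab, age) {
  ages <- as.integer(names(tab))
  a <- pmin(pmax(round(age), min(ages)), max(ages))
  unname(tab[match(a, ages)])
}

.mortality_at <- function(params, age) {
  .age_lookup(params$epidemiology$all_cause_mortality, age)
}

.u_healthy_at <- function(params, age) {
  .age_lookup(params$utilities$u_healthy, age)
}

#' @export
print.zoster_params <- function(x, ...) {
  bands <- age_bands()$label
  cat("Herpes zoster CEA parameter set\n")
  cat("  Age bands:        ", paste(bands, collapse = ", "), "\n")
  cat("  HZ incidence:     ",
      paste(sprintf("%.4f", x$epidemiology$hz_incidence), collapse = ", "),
      "(per person-year, by band)\n")
  cat("  P(PHN | HZ):      ",
      paste(sprintf("%.2f", x$epidemiology$p_phn_given_hz), collapse = ", "),
      "\n")
  cat(sprintf("  Vaccine prices:    RZV %.2f x2 doses, ZVL %.2f x1 dose, admin %.2f/dose (USD)\n",
              x$costs$price_rzv_dose, x$costs$price_zvl_dose,
              x$costs$cost_admin_dose))
  cat(sprintf("  Utilities:         HZ %.2f, PHN %.2f\n",
              x$utilities$u_hz, x$utilities$u_phn))
  cat(sprintf("  Economics:         discount %.1f%%, horizon %d y, WTP %s USD/QALY\n",
              100 * x$economics$discount_rate, x$economics$horizon,
              format(x$economics$wtp, big.mark = ",")))
  cat(sprintf("  Sensitivity specs: %d PSA, %d one-way parameters\n",
              length(x$psa_spec), length(x$owsa_spec)))
  invisible(x)
}
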