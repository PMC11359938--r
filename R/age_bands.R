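# Age stratification used throughout the model: four bands covering [50, Inf).

.zoster_states <- c("Healthy", "AcuteHZ", "PHN", "OtherComplication",
                    "HZResolved", "Dead")

.zoster_strategies <- c("NoVaccination", "ZVL", "RZV")

#' Age bands of the cohort model
#'
#' The model stratifies all herpes zoster epidemiology by four attained-age
#' bands: 50-59, 60-69, 70-79 and 80+ years. The last band is open-ended.
#'
#' @return A data.frame with columns `label`, `lower` and `upper` (upper bound
#'   exclusive; `Inf` for the last band).
#' @examples
#' age_bands()
#' @export
age_bands <- function() {
  data.frame(
    label = c("50-59", "60-69", "70-79", "80+"),
    lower = c(50, 60, 70, 80),
    upper = c(60, 70, 80, Inf),
    stringsAsFactors = FALSE
  )
}

#' Map an age to its model age band
#'
#' @param age Numeric vector of ages in years. All ages must be at least 50,
#'   the youngest age the model covers.
#' @return Character vector of band labels (`"50-59"`, `"60-69"`, `"70-79"`,
#'   `"80+"`).
#' @examples
#' band_of(c(50, 59, 60, 95))
#' @export
band_of <- function(age) {
  if (!is.numeric(age) || any(!is.finite(age))) {
    stop("`age` must be finite numeric", call. = FALSE)
  }
  if (any(age < 50)) {
    stop("the model covers ages 50 and older; got age ", min(age), call. = FALSE)
  }
  bands <- age_bands()
  idx <- findInterval(age, bands$lower)
  bands$label[idx]
}

.state_index <- function(state) match(state, .zoster_states)

.match_strategy <- function(strategy) {
  match.arg(strategy, .zoster_strategies)
}
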