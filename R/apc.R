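#' Age-period-cohort hazard parameters
#'
#' The multiplicative mortality model: the 1950 single-age rate table is
#' the age effect, the period coefficient `p` scales mortality by
#' `p^(year - 1950)`, and the cohort coefficient `c` by
#' `c^(birth_year - reference)`, with the earliest cohort (1880) as the
#' reference. The CVD share of total mortality varies by year only.
#'
#' @param m1950 Matrix ages x sex of 1950 mortality rates (per person-year),
#'   rownames single ages.
#' @param p Named numeric (per sex) period coefficient, > 0.
#' @param c Named numeric (per sex) cohort coefficient, > 0.
#' @param cvd_proportion Named numeric (names = years) CVD share of total
#'   mortality, in \[0, 1\].
#' @param cohort_reference_year Birth year at which the cohort effect is 1.
#' @param period_reference_year Calendar year at which the period effect
#'   is 1.
#' @return A list of class `apc_params`.
#' @export
apc_params <- function(m1950, p, c, cvd_proportion,
                       cohort_reference_year = 1880L,
                       period_reference_year = 1950L) {
  .chk(all(m1950 >= 0 & m1950 < 1), "m1950 rates must lie in [0, 1)")
  .chk(all(p > 0) && all(c > 0), "p and c must be positive")
  .chk(all(cvd_proportion >= 0 & cvd_proportion <= 1),
       "cvd_proportion must lie in [0, 1]")
  if (length(p) == 1L && is.null(names(p))) p <- stats::setNames(rep(p, 2), SEXES)
  if (length(c) == 1L && is.null(names(c))) c <- stats::setNames(rep(c, 2), SEXES)
  structure(list(m1950 = m1950, p = p, c = c,
                 cvd_proportion = cvd_proportion,
                 cohort_reference_year = as.integer(cohort_reference_year),
                 period_reference_year = as.integer(period_reference_year)),
            class = "apc_params")
}

#' Total mortality hazard from the multiplicative APC model
#'
#' `m1950(age, sex) * p^(year - 1950) * c^(birth_year - reference)` with
#' `birth_year = year - age`. Vectorised over `age` and `year`.
#'
#' @param age Completed years at the start of `year` (within the m1950
#'   table).
#' @param year Calendar year (>= the period reference).
#' @param sex `"male"` or `"female"`.
#' @param params An [apc_params()].
#' @return Hazard per person-year.
#' @export
baseline_hazard <- function(age, year, sex, params) {
  a <- as.character(age)
  .chk(all(a %in% rownames(params$m1950)), "age outside the m1950 table")
  params$m1950[cbind(a, sex)] *
    params$p[[sex]] ^ (year - params$period_reference_year) *
    params$c[[sex]] ^ ((year - age) - params$cohort_reference_year)
}

#' Salt-effect parameters
#'
#' A 10 mmol/day (0.584 g/day) higher salt intake is associated with a 1%
#' higher CVD mortality; the effect is split 1:1 between the period channel
#' (intake difference now) and the cohort channel (difference at age 20),
#' and applies only from age 20.
#'
#' @param percent_per_unit Percent CVD mortality change per unit of salt.
#' @param grams_per_unit Grams of salt per effect unit (10 mmol sodium).
#' @param period_weight,cohort_weight Channel weights; must sum to 1.
#' @param min_effect_age Youngest age at which salt differences act.
#' @param form `"power"` (default) applies the effect as
#'   `(1 + pct/100)^(units)`, which composes across channels and stays
#'   positive; `"linear"` applies `1 + (pct/100) * units`.
#' @return A list of class `salt_effect_params`.
#' @export
salt_effect_params <- function(percent_per_unit = 1, grams_per_unit = 0.584,
                               period_weight = 0.5, cohort_weight = 0.5,
                               min_effect_age = 20L,
                               form = c("power", "linear")) {
  .chk(isTRUE(all.equal(period_weight + cohort_weight, 1)),
       "period_weight + cohort_weight must equal 1")
  .chk(grams_per_unit > 0, "grams_per_unit must be positive")
  structure(list(percent_per_unit = percent_per_unit,
                 grams_per_unit = grams_per_unit,
                 period_weight = period_weight,
                 cohort_weight = cohort_weight,
                 min_effect_age = as.integer(min_effect_age),
                 form = match.arg(form)),
            class = "salt_effect_params")
}

#' CVD-mortality multiplier for a salt-intake difference
#'
#' For ages at or above `min_effect_age`, the weighted gram difference
#' `w_p * delta_period + w_c * delta_cohort` is converted to effect units
#' of `grams_per_unit` and applied as `(1 + pct/100)^units` (power form).
#' A sustained difference of one unit in both channels therefore yields
#' exactly the stated percent increase. Below `min_effect_age` the
#' multiplier is 1. Vectorised; negative differences give multipliers
#' below 1.
#'
#' @param delta_period Assumed minus actual intake (g/day) at the current
#'   year and age.
#' @param delta_cohort Assumed minus actual intake (g/day) at age 20 for
#'   the cohort.
#' @param age Completed years.
#' @param se A [salt_effect_params()].
#' @return Dimensionless multiplier > 0.
#' @export
salt_effect_multiplier <- function(delta_period, delta_cohort, age,
                                   se = salt_effect_params()) {
  .chk(all(is.finite(delta_period)) && all(is.finite(delta_cohort)),
       "salt differences must be finite")
  units <- (se$period_weight * delta_period +
            se$cohort_weight * delta_cohort) / se$grams_per_unit
  mult <- if (se$form == "power") {
    (1 + se$percent_per_unit / 100) ^ units
  } else {
    pmax(1 + (se$percent_per_unit / 100) * units, 0)
  }
  n <- max(length(mult), length(age))
  mult <- rep_len(mult, n)
  mult[rep_len(age, n) < se$min_effect_age] <- 1
  mult
}

#' Split a total hazard into CVD and other-cause hazards
#'
#' `cvd = total * proportion(year) * multiplier`;
#' `other = total * (1 - proportion(year))`. The other-cause hazard does
#' not depend on the salt multiplier, so it is identical across scenarios.
#'
#' @param total_hazard Total mortality hazard per person-year (>= 0).
#' @param year Calendar year (must be in the proportion table).
#' @param multiplier Salt-effect multiplier (> 0).
#' @param params An [apc_params()].
#' @return List with components `cvd` and `other`.
#' @export
cause_specific_hazards <- function(total_hazard, year, multiplier, params) {
  .chk(all(total_hazard >= 0), "total hazard must be non-negative")
  .chk(all(multiplier > 0), "multiplier must be positive")
  y <- as.character(year)
  .chk(all(y %in% names(params$cvd_proportion)),
       "year outside the cvd_proportion table")
  prop <- params$cvd_proportion[y]
  list(cvd = unname(total_hazard * prop * multiplier),
       other = unname(total_hazard * (1 - prop)))
}
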