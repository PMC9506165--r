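#' Salt-imputation configuration
#'
#' Parameters of the salt-surface reconstruction: the window of overall
#' survey means used to fit the back-extrapolation line, how far back the
#' line is extended (to 1900, so the earliest cohort has an age-20 value),
#' the plausibility cap on extrapolated male intake in 1942 and earlier,
#' and the reference window over which sex x age-group ratios are taken.
#'
#' @param fit_window Years of the overall series used for the OLS trend fit.
#' @param backcast_start_year First year of the extrapolated series.
#' @param male_cap Upper bound (g/day) on male values in `cap_year` and
#'   earlier.
#' @param cap_year Last year to which `male_cap` applies.
#' @param ratio_reference_window Years over which group/overall mean ratios
#'   are computed.
#' @return A list of class `imputation_config`.
#' @export
imputation_config <- function(fit_window = c(1973L, 1986L),
                              backcast_start_year = 1900L,
                              male_cap = 20, cap_year = 1942L,
                              ratio_reference_window = c(1995L, 2017L)) {
  .chk(male_cap > 0, "male_cap must be positive")
  .chk(fit_window[2] >= fit_window[1], "invalid fit_window")
  structure(list(fit_window = as.integer(fit_window),
                 backcast_start_year = as.integer(backcast_start_year),
                 male_cap = as.numeric(male_cap),
                 cap_year = as.integer(cap_year),
                 ratio_reference_window = as.integer(ratio_reference_window)),
            class = "imputation_config")
}

#' Fit the back-extrapolation line to an overall salt series
#'
#' Ordinary least squares on the overall annual means inside the fit
#' window; the fitted line supplies pre-survey overall values.
#'
#' @param years Integer years of the series.
#' @param values Overall mean salt intake (g/day) per year.
#' @param window Length-2 year range used for the fit.
#' @return A list of class `backcast_line` with `slope` (g/day per year),
#'   `intercept` (g/day at year 0) and the window used.
#' @export
fit_backcast_line <- function(years, values, window = c(1973L, 1986L)) {
  keep <- years >= window[1] & years <= window[2]
  .chk(sum(keep) >= 2L, "need at least 2 points inside the fit window")
  fit <- stats::lm(values[keep] ~ years[keep])
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 window = as.integer(window)),
            class = "backcast_line")
}

#' Evaluate the back-extrapolation line over pre-survey years
#'
#' Evaluates the fitted line year by year. Male values in `cap_year`
#' (1942) and earlier are clamped to `male_cap` (20 g/day); female values
#' are used as fitted.
#'
#' @param line A `backcast_line` from [fit_backcast_line()].
#' @param years Years to evaluate (typically preceding the survey series).
#' @param sex `"male"` or `"female"` (controls the cap).
#' @param cfg An [imputation_config()].
#' @return Named numeric vector of g/day values, names are years.
#' @export
backcast_overall <- function(line, years, sex = "male",
                             cfg = imputation_config()) {
  stopifnot(inherits(line, "backcast_line"))
  vals <- line$intercept + line$slope * years
  if (identical(sex, "male"))
    vals[years <= cfg$cap_year] <- pmin(vals[years <= cfg$cap_year],
                                        cfg$male_cap)
  .chk(all(vals > 0), "back-extrapolated salt intake is non-positive")
  stats::setNames(vals, as.character(years))
}

#' Sex x age-group to overall intake ratios
#'
#' For each sex and 10-year age group, the ratio of the arithmetic mean of
#' the group means over the reference window to the arithmetic mean of the
#' overall means over the same window.
#'
#' @param group_means Data frame `sex, year, age_group_start, age_group_end,
#'   grams_per_day`.
#' @param overall_means Data frame `sex, year, grams_per_day` covering the
#'   reference window (`sex = "all"` accepted for a combined series).
#' @param window Length-2 reference year range.
#' @return Data frame `sex, age_group_start, age_group_end, ratio`.
#' @export
group_ratios <- function(group_means, overall_means,
                         window = c(1995L, 2017L)) {
  g <- group_means[group_means$year >= window[1] &
                   group_means$year <= window[2], , drop = FALSE]
  .chk(nrow(g) > 0, "no group means inside the reference window")
  out <- do.call(rbind, lapply(split(
    g, list(g$sex, g$age_group_start), drop = TRUE), function(d) {
      o <- overall_means[(overall_means$sex == d$sex[1] |
                          overall_means$sex == "all") &
                         overall_means$year >= window[1] &
                         overall_means$year <= window[2], , drop = FALSE]
      .chk(nrow(o) > 0, "overall means do not cover the reference window")
      denom <- mean(o$grams_per_day)
      .chk(denom != 0, "zero overall mean in the reference window")
      data.frame(sex = d$sex[1],
                 age_group_start = d$age_group_start[1],
                 age_group_end = d$age_group_end[1],
                 ratio = mean(d$grams_per_day) / denom)
    }))
  out <- out[order(out$sex, out$age_group_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## map a single age to the row of the ratio table for one sex; ages below
## the youngest surveyed group take the youngest group's entry
.group_index <- function(ages, starts, ends) {
  idx <- rep(NA_integer_, length(ages))
  for (i in seq_along(starts))
    idx[ages >= starts[i] & ages <= ends[i]] <- i
  idx[ages < min(starts)] <- which.min(starts)
  .chk(!anyNA(idx), "missing age-group ratio for some ages")
  idx
}

#' Build the salt-intake surface by year x single age x sex
#'
#' Years up to 1994 take the overall mean (published or back-extrapolated)
#' scaled by the sex x age-group ratio, constant across single ages within
#' each 10-year group; years from 1995 pass the reported group means
#' through unchanged. Single ages below the youngest surveyed group take
#' that group's ratio/value. Male cells in `cap_year` and earlier are
#' clamped to `male_cap` after scaling, matching the cap on the overall
#' extrapolation.
#'
#' @param overall Named numeric vector (names = years) of overall g/day
#'   values per sex-relevant year, covering `backcast_start_year`-1994.
#' @param ratios The rows of [group_ratios()] output for one sex.
#' @param group_values Data frame of reported group means for one sex over
#'   1995 onwards.
#' @param sex `"male"` or `"female"`.
#' @param ages Integer vector of single ages.
#' @param end_year Last year of the surface.
#' @param cfg An [imputation_config()].
#' @return Matrix ages x years of g/day values.
#' @export
build_salt_matrix <- function(overall, ratios, group_values, sex,
                              ages = 0:69, end_year = 2017L,
                              cfg = imputation_config()) {
  years <- cfg$backcast_start_year:end_year
  scaled_years <- years[years <= 1994L]
  .chk(all(as.character(scaled_years) %in% names(overall)),
       "overall series does not cover ", cfg$backcast_start_year, "-1994")
  m <- matrix(NA_real_, length(ages), length(years),
              dimnames = list(as.character(ages), as.character(years)))
  gi <- .group_index(ages, ratios$age_group_start, ratios$age_group_end)
  m[, as.character(scaled_years)] <-
    outer(ratios$ratio[gi], overall[as.character(scaled_years)])
  for (t in years[years >= 1995L]) {
    gv <- group_values[group_values$year == t, , drop = FALSE]
    .chk(nrow(gv) > 0, "no reported group values for year ", t)
    idx <- .group_index(ages, gv$age_group_start, gv$age_group_end)
    m[, as.character(t)] <- gv$grams_per_day[idx]
  }
  if (identical(sex, "male")) {
    capped <- years <= cfg$cap_year
    m[, capped] <- pmin(m[, capped, drop = FALSE], cfg$male_cap)
  }
  .chk(all(m > 0), "salt surface contains non-positive values")
  m
}

#' Per-cohort salt intake at age 20
#'
#' `salt_at_20(b, sex) = surface(year = b + 20, age = 20, sex)`.
#'
#' @param surface A `salt_surface` object, or a list of per-sex age x year
#'   matrices.
#' @param cohorts Birth years.
#' @return List per sex of named numeric vectors (names = birth years).
#' @export
salt_at_age20 <- function(surface, cohorts = COHORT_YEARS) {
  mats <- if (inherits(surface, "salt_surface")) surface$surface else surface
  lapply(mats, function(m) {
    yrs <- as.character(cohorts + 20L)
    .chk(all(yrs %in% colnames(m)),
         "surface does not cover age-20 years for all cohorts")
    stats::setNames(m["20", yrs], as.character(cohorts))
  })
}

#' Reconstruct the salt-exposure surface from survey tables
#'
#' The full imputation pipeline: per sex, fit the back-extrapolation line
#' on the overall series (1973-1986 by default), extrapolate to
#' `backcast_start_year` with the male cap, compute sex x age-group ratios
#' over the reference window, scale the overall series into single-age
#' values up to 1994, pass reported group means through from 1995, and
#' derive each cohort's intake at age 20. If the overall series does not
#' cover the ratio reference window (the survey design: overall means end
#' in 1994), per-year overall values in the window are derived as the
#' unweighted mean of that sex's adult group means.
#'
#' @param salt_overall Data frame `sex, year, grams_per_day`; `sex = "all"`
#'   is applied to both sexes.
#' @param salt_groups Data frame `sex, year, age_group_start, age_group_end,
#'   grams_per_day`.
#' @param cfg An [imputation_config()].
#' @param cohorts Birth years needing an age-20 value.
#' @param ages Single ages of the surface.
#' @param end_year Last surface year.
#' @return A list of class `salt_surface`: `surface` (per-sex age x year
#'   matrices), `at20` (per-sex named vectors by birth year), `ratios`,
#'   `lines` (per-sex backcast fits).
#' @export
impute_salt <- function(salt_overall, salt_groups, cfg = imputation_config(),
                        cohorts = COHORT_YEARS, ages = 0:69,
                        end_year = 2017L) {
  win <- cfg$ratio_reference_window
  surf <- list(); lines <- list()
  all_ratios <- NULL
  for (s in SEXES) {
    o <- salt_overall[salt_overall$sex %in% c(s, "all"), , drop = FALSE]
    .chk(nrow(o) > 0, "no overall salt series for sex '", s, "'")
    g <- salt_groups[salt_groups$sex == s, , drop = FALSE]
    .chk(nrow(g) > 0, "no group salt series for sex '", s, "'")

    ## overall values inside the ratio window: published if present, else
    ## derived as the per-year mean of the group means
    in_win <- o[o$year >= win[1] & o$year <= win[2], , drop = FALSE]
    if (!all(win[1]:win[2] %in% in_win$year)) {
      gw <- g[g$year >= win[1] & g$year <= win[2], , drop = FALSE]
      derived <- stats::aggregate(grams_per_day ~ year, gw, mean)
      derived <- derived[!(derived$year %in% in_win$year), , drop = FALSE]
      if (nrow(derived) > 0)
        in_win <- rbind(in_win, data.frame(sex = s, year = derived$year,
                                           grams_per_day = derived$grams_per_day))
    }
    ratios <- group_ratios(g, in_win, window = win)
    all_ratios <- rbind(all_ratios, ratios)

    line <- fit_backcast_line(o$year, o$grams_per_day, cfg$fit_window)
    lines[[s]] <- line
    pre_years <- cfg$backcast_start_year:(min(o$year) - 1L)
    bc <- backcast_overall(line, pre_years, sex = s, cfg = cfg)
    pub <- o[o$year <= 1994L, , drop = FALSE]
    overall_full <- c(bc, stats::setNames(pub$grams_per_day,
                                          as.character(pub$year)))
    surf[[s]] <- build_salt_matrix(overall_full, ratios, g, sex = s,
                                   ages = ages, end_year = end_year,
                                   cfg = cfg)
  }
  out <- structure(list(surface = surf, at20 = NULL, ratios = all_ratios,
                        lines = lines, cfg = cfg),
                   class = "salt_surface")
  out$at20 <- salt_at_age20(out, cohorts = cohorts)
  out
}

#' Counterfactual ("assumed") salt surface for an effect fraction
#'
#' For years at or after the anchor, the assumed intake retains a fraction
#' `f` of the actual change since the anchor year:
#' `assumed(t) = actual(t) + (1 - f) * (actual(anchor) - actual(t))`.
#' `f = 1` reproduces the actual surface; `f = 0` freezes intake at its
#' anchor-year level. Years before the anchor are unchanged, so cohorts
#' reaching age 20 before the anchor keep their actual age-20 intake.
#'
#' @param surface A `salt_surface`.
#' @param fraction Effect fraction `f` in \[0, 1\].
#' @param anchor_year Year whose intake defines "no change" (1950).
#' @return A `salt_surface` with the assumed surface and its own `at20`.
#' @export
counterfactual_salt <- function(surface, fraction, anchor_year = 1950L) {
  stopifnot(inherits(surface, "salt_surface"))
  .chk(length(fraction) == 1L && fraction >= 0 && fraction <= 1,
       "effect fraction must lie in [0, 1]")
  if (fraction == 1) return(surface)
  out <- surface
  for (s in names(surface$surface)) {
    m <- surface$surface[[s]]
    yrs <- as.integer(colnames(m))
    .chk(as.character(anchor_year) %in% colnames(m),
         "anchor year outside surface")
    anchor <- m[, as.character(anchor_year)]
    post <- yrs >= anchor_year
    m[, post] <- m[, post, drop = FALSE] +
      (1 - fraction) * (anchor - m[, post, drop = FALSE])
    out$surface[[s]] <- m
  }
  out$at20 <- salt_at_age20(out, cohorts = as.integer(names(surface$at20[[1]])))
  out
}

#' @export
print.salt_surface <- function(x, ...) {
  m <- x$surface[[1]]
  cat("Salt-exposure surface\n")
  cat("  years:", colnames(m)[1], "-", colnames(m)[ncol(m)],
      "| ages:", rownames(m)[1], "-", rownames(m)[nrow(m)], "\n")
  for (s in names(x$surface))
    cat(sprintf("  %s: %.1f-%.1f g/day\n", s, min(x$surface[[s]]),
                max(x$surface[[s]])))
  invisible(x)
}
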