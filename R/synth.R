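#' Synthetic-bundle configuration
#'
#' Parameters of the synthetic input generator, chosen to emulate the
#' statistical structure of the postwar Japanese sources the model
#' consumes: an exponentially tapering 1950 pyramid, births declining 1%
#' per year, a Gompertz 1950 mortality schedule with an infant offset, a
#' CVD proportion that rises to 1970 then eases, smoothly declining salt
#' paths with a mid-age peak and young-adult trough, and APC coefficient
#' truths defaulting to the calibrated values the model is expected to
#' recover.
#'
#' @param seed Integer seed for any observation noise.
#' @param birth_level Total births (both sexes) in 1950, persons/year.
#' @param birth_decline Proportional annual decline in births.
#' @param male_birth_fraction Share of births that are male.
#' @param pyramid_base 1950 population at age 0 (both sexes combined).
#' @param pyramid_taper Exponential decline of the 1950 pyramid per year
#'   of age.
#' @param gompertz_a,gompertz_b 1950 mortality schedule
#'   `a * exp(b * age)`.
#' @param infant_rate Added infant mortality, decaying as `exp(-age)`.
#' @param sex_mortality_mult Named multipliers on the 1950 schedule.
#' @param cvd_start,cvd_peak,cvd_end CVD proportion path: `cvd_start` in
#'   1950 rising linearly to `cvd_peak` in `cvd_peak_year`, then easing
#'   linearly to `cvd_end` in 2017.
#' @param cvd_peak_year Year of the CVD-proportion peak.
#' @param salt_start,salt_end Named (per sex) overall salt means (g/day)
#'   at the plateau year and 2017.
#' @param salt_plateau_year Intake is flat at `salt_start` before this
#'   year and declines linearly to 2017 after it, so the pre-survey trend
#'   the imputation back-extrapolates is exactly linear.
#' @param age_group_ratios Relative intake by 10-year age group (20s
#'   through 60s), normalised internally to mean 1 so the group means are
#'   consistent with the overall mean.
#' @param true_p,true_c Named (per sex) generating period and cohort
#'   coefficients.
#' @param sigma Lognormal observation noise (sd of log rates) on the
#'   observed mortality surface; 0 keeps the bundle fully deterministic.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         birth_level = 1.5e6, birth_decline = 0.01,
                         male_birth_fraction = 0.512,
                         pyramid_base = 1.8e6, pyramid_taper = 0.03,
                         gompertz_a = 5e-5, gompertz_b = 0.085,
                         infant_rate = 0.02,
                         sex_mortality_mult = c(male = 1.1, female = 0.9),
                         cvd_start = 0.20, cvd_peak = 0.40, cvd_end = 0.30,
                         cvd_peak_year = 1970L,
                         salt_start = c(male = 20, female = 14),
                         salt_end = c(male = 11, female = 9),
                         salt_plateau_year = 1940L,
                         age_group_ratios = c(0.90, 1.00, 1.05, 1.10, 1.05),
                         true_p = c(male = 0.97777, female = 0.962632),
                         true_c = c(male = 0.999826, female = 0.998483),
                         sigma = 0) {
  .chk(sigma >= 0, "sigma must be non-negative")
  .chk(all(salt_start > 0 & salt_start < 25) && all(salt_end > 0),
       "salt paths must lie within (0, 25) g/day")
  .chk(all(true_p > 0) && all(true_c > 0), "true coefficients must be positive")
  structure(list(seed = as.integer(seed), birth_level = birth_level,
                 birth_decline = birth_decline,
                 male_birth_fraction = male_birth_fraction,
                 pyramid_base = pyramid_base, pyramid_taper = pyramid_taper,
                 gompertz_a = gompertz_a, gompertz_b = gompertz_b,
                 infant_rate = infant_rate,
                 sex_mortality_mult = sex_mortality_mult,
                 cvd_start = cvd_start, cvd_peak = cvd_peak,
                 cvd_end = cvd_end, cvd_peak_year = as.integer(cvd_peak_year),
                 salt_start = salt_start, salt_end = salt_end,
                 salt_plateau_year = as.integer(salt_plateau_year),
                 age_group_ratios = age_group_ratios / mean(age_group_ratios),
                 true_p = true_p, true_c = true_c, sigma = sigma),
            class = "synth_config")
}

.synth_m1950 <- function(cfg, ages = MODEL_AGES) {
  base <- cfg$gompertz_a * exp(cfg$gompertz_b * ages) +
    cfg$infant_rate * exp(-ages)
  m <- sapply(SEXES, function(s) base * cfg$sex_mortality_mult[[s]])
  rownames(m) <- as.character(ages)
  .chk(all(m < 1), "synthetic 1950 rates reach 1; lower the schedule")
  m
}

#' Generate the demographic input tables
#'
#' Deterministic given the configuration: the 1950 pyramid, the annual
#' births, the 1950 mortality schedule and the CVD proportion path, as
#' the data frames [salt_bundle()] consumes.
#'
#' @param cfg A [synth_config()].
#' @param config A [run_config()] fixing the axes.
#' @return List with `initial_population`, `births`, `mortality_1950`,
#'   `cvd_proportion` data frames.
#' @export
generate_demography <- function(cfg = synth_config(), config = run_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  years <- config$start_year:config$end_year
  birth_years <- config$start_year:config$max_cohort_year
  sex_frac <- c(male = cfg$male_birth_fraction,
                female = 1 - cfg$male_birth_fraction)
  init <- do.call(rbind, lapply(SEXES, function(s)
    data.frame(sex = s, age = INIT_AGES,
               population = cfg$pyramid_base * sex_frac[[s]] *
                 exp(-cfg$pyramid_taper * INIT_AGES))))
  births <- do.call(rbind, lapply(SEXES, function(s)
    data.frame(sex = s, year = birth_years,
               births = cfg$birth_level * sex_frac[[s]] *
                 (1 - cfg$birth_decline) ^ (birth_years - config$start_year))))
  m <- .synth_m1950(cfg)
  m1950 <- do.call(rbind, lapply(SEXES, function(s)
    data.frame(sex = s, age = MODEL_AGES, rate = m[, s])))
  prop <- ifelse(years <= cfg$cvd_peak_year,
                 cfg$cvd_start + (cfg$cvd_peak - cfg$cvd_start) *
                   (years - config$start_year) /
                   (cfg$cvd_peak_year - config$start_year),
                 cfg$cvd_peak + (cfg$cvd_end - cfg$cvd_peak) *
                   (years - cfg$cvd_peak_year) /
                   (config$end_year - cfg$cvd_peak_year))
  list(initial_population = init, births = births, mortality_1950 = m1950,
       cvd_proportion = data.frame(year = years, proportion = prop))
}

## overall salt level per sex and year: plateau then linear decline
.synth_salt_level <- function(cfg, years, sex) {
  t0 <- cfg$salt_plateau_year
  start <- cfg$salt_start[[sex]]; end <- cfg$salt_end[[sex]]
  slope <- (end - start) / (2017 - t0)
  ifelse(years <= t0, start, start + slope * (years - t0))
}

#' True salt-exposure surface of the generator
#'
#' `level(year, sex) * ratio(age group)` on the full age x year grid; the
#' imputation module's reconstruction error is measured against this.
#'
#' @param cfg A [synth_config()].
#' @param years,ages Surface axes.
#' @return A `salt_surface` object.
#' @export
generate_true_salt <- function(cfg = synth_config(), years = 1900:2017,
                               ages = MODEL_AGES) {
  starts <- seq(20L, 60L, 10L)
  gi <- .group_index(ages, starts, starts + 9L)
  surf <- lapply(stats::setNames(SEXES, SEXES), function(s) {
    m <- outer(cfg$age_group_ratios[gi], .synth_salt_level(cfg, years, s))
    dimnames(m) <- list(as.character(ages), as.character(years))
    m
  })
  out <- structure(list(surface = surf, at20 = NULL, ratios = NULL,
                        lines = NULL, cfg = NULL), class = "salt_surface")
  out$at20 <- salt_at_age20(out)
  out
}

#' Generate the salt survey tables
#'
#' Emulates the survey design the imputation module expects: overall
#' annual means from 1973 (exactly linear over the back-extrapolation fit
#' window by construction) and means by sex and 10-year age group from
#' 1995, both sampled from one underlying smooth true surface.
#'
#' @param cfg A [synth_config()].
#' @param overall_years Years of the overall series. The default extends
#'   to 2017 so the ratio reference window is covered; pass
#'   `1973:1994` to emulate the historical design (the imputation then
#'   derives window overall means from the group table).
#' @param group_years Years of the by-group series.
#' @return List with `salt_overall` and `salt_groups` data frames.
#' @export
generate_salt_surveys <- function(cfg = synth_config(),
                                  overall_years = 1973:2017,
                                  group_years = 1995:2017) {
  starts <- seq(20L, 60L, 10L)
  overall <- do.call(rbind, lapply(SEXES, function(s)
    data.frame(sex = s, year = overall_years,
               grams_per_day = .synth_salt_level(cfg, overall_years, s))))
  groups <- do.call(rbind, lapply(SEXES, function(s)
    do.call(rbind, lapply(seq_along(starts), function(i)
      data.frame(sex = s, year = group_years,
                 age_group_start = starts[i], age_group_end = starts[i] + 9L,
                 grams_per_day = cfg$age_group_ratios[i] *
                   .synth_salt_level(cfg, group_years, s))))))
  list(salt_overall = overall, salt_groups = groups)
}

#' Generate an observed mortality surface from the APC model
#'
#' The model rate surface at the generating truth `(p, c)`, optionally
#' perturbed cell-wise by lognormal noise `exp(N(0, sigma^2))` under the
#' given seed.
#'
#' @param m1950 Matrix ages x sex of 1950 rates.
#' @param true_p,true_c Named (per sex) generating coefficients.
#' @param sigma Sd of the log-rate noise (0 for a noiseless surface).
#' @param seed Seed used when `sigma > 0`.
#' @param years Grid years.
#' @return Per-sex list of age x year rate matrices.
#' @export
generate_observed_mortality <- function(m1950, true_p, true_c, sigma = 0,
                                        seed = 1L, years = MODEL_YEARS) {
  .chk(sigma >= 0, "sigma must be non-negative")
  if (sigma > 0) set.seed(seed)
  lapply(stats::setNames(SEXES, SEXES), function(s) {
    m <- model_rate_surface(m1950[, s], true_p[[s]], true_c[[s]],
                            ages = as.integer(rownames(m1950)),
                            years = years)
    if (sigma > 0)
      m <- m * exp(matrix(stats::rnorm(length(m), 0, sigma), nrow(m)))
    ## keep the noisy surface a valid rate table
    pmin(m, 1 - 1e-9)
  })
}

#' Generate a complete synthetic input bundle
#'
#' Demography, salt surveys and an observed mortality surface generated
#' from the APC model at the configured truth, assembled into a validated
#' `salt_bundle`. The generating truth (coefficients and true salt
#' surface) is attached as the `truth` element so recovery can be
#' measured; [write_bundle()] does not write it.
#'
#' @param cfg A [synth_config()].
#' @param config A [run_config()].
#' @param dir Optional directory: when given, the bundle is also written
#'   as the seven input CSVs.
#' @return A `salt_bundle` with an extra `truth` element
#'   (`p`, `c`, `salt`).
#' @export
generate_bundle <- function(cfg = synth_config(), config = run_config(),
                            dir = NULL) {
  demo <- generate_demography(cfg, config)
  surveys <- generate_salt_surveys(cfg)
  m <- .synth_m1950(cfg)
  obs <- generate_observed_mortality(m, cfg$true_p, cfg$true_c,
                                     sigma = cfg$sigma, seed = cfg$seed,
                                     years = config$start_year:config$end_year)
  obs_df <- do.call(rbind, lapply(SEXES, function(s) {
    g <- expand.grid(age = as.integer(rownames(obs[[s]])),
                     year = as.integer(colnames(obs[[s]])))
    data.frame(sex = s, year = g$year, age = g$age,
               rate = as.vector(obs[[s]]))
  }))
  bundle <- salt_bundle(demo$initial_population, demo$births,
                        demo$mortality_1950, demo$cvd_proportion,
                        obs_df, surveys$salt_overall, surveys$salt_groups,
                        config = config)
  bundle$truth <- list(p = cfg$true_p, c = cfg$true_c,
                       salt = generate_true_salt(cfg))
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}
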