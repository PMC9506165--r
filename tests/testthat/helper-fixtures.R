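## Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

## deterministic synthetic bundle at the default study conditions
test_bundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- generate_bundle(synth_config(seed = 1))
  .fixtures$bundle
}

test_fit <- function() {
  if (is.null(.fixtures$fit))
    .fixtures$fit <- salt_apc(test_bundle())
  .fixtures$fit
}

## all five scenarios from the fitted model
test_scenarios <- function() {
  if (is.null(.fixtures$scen))
    .fixtures$scen <- simulate(test_fit())
  .fixtures$scen
}

## a salt surface that is constant everywhere: multiplier-neutral inputs
flat_salt <- function(value = 12, years = 1900:2017, ages = 0:69,
                      cohorts = 1880:1997) {
  m <- matrix(value, length(ages), length(years),
              dimnames = list(as.character(ages), as.character(years)))
  s <- structure(list(surface = list(male = m, female = m), at20 = NULL),
                 class = "salt_surface")
  s$at20 <- salt_at_age20(s, cohorts = cohorts)
  s
}

## minimal single-cohort bundle for hand-checkable engine runs
toy_bundle <- function(pop0 = 1000, m0 = 0.01, m1 = 0.02,
                       prop = c(0.3, 0.4)) {
  cfg <- run_config(start_year = 1950, end_year = 1951,
                    min_cohort_year = 1950, max_cohort_year = 1950)
  ages <- 0:69
  m1950 <- data.frame(sex = rep(c("male", "female"), each = 70),
                      age = rep(ages, 2), rate = 0.005)
  m1950$rate[m1950$age == 0] <- m0
  m1950$rate[m1950$age == 1] <- m1
  salt_bundle(
    initial_population = data.frame(
      sex = rep(c("male", "female"), each = 71),
      age = rep(0:70, 2), population = 0),
    births = data.frame(sex = c("male", "female"),
                        year = 1950, births = pop0),
    mortality_1950 = m1950,
    cvd_proportion = data.frame(year = 1950:1951, proportion = prop),
    observed_mortality = data.frame(
      sex = rep(c("male", "female"), each = 140),
      year = rep(rep(1950:1951, each = 70), 2),
      age = rep(ages, 4), rate = 0.005),
    salt_overall = data.frame(sex = "all", year = 1973:1994,
                              grams_per_day = 12),
    salt_groups = data.frame(sex = rep(c("male", "female"), each = 5),
                             year = 1995,
                             age_group_start = rep(seq(20, 60, 10), 2),
                             age_group_end = rep(seq(29, 69, 10), 2),
                             grams_per_day = 12),
    config = cfg)
}
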