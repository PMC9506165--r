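#' Initialise the cohort stocks
#'
#' Cohorts born before the start year enter the simulation in the start
#' year with the initial-population stock at their then-current age;
#' cohorts born during the simulation enter in their birth year with that
#' year's birth count. A cohort that has already reached the exit age at
#' the start (the 1880 cohort, aged 70 in 1950) is instantiated but
#' inactive and contributes no person-time.
#'
#' @param bundle A `salt_bundle`.
#' @param cfg A [run_config()] (defaults to the bundle's).
#' @return Data frame `sex, birth_year, start_year, population, active`,
#'   one row per cohort x sex.
#' @export
init_cohorts <- function(bundle, cfg = bundle$config) {
  cohorts <- cfg$min_cohort_year:cfg$max_cohort_year
  out <- do.call(rbind, lapply(SEXES, function(s) {
    pop <- numeric(length(cohorts))
    start <- integer(length(cohorts))
    active <- logical(length(cohorts))
    for (i in seq_along(cohorts)) {
      b <- cohorts[i]
      if (b < cfg$start_year) {
        age0 <- cfg$start_year - b
        .chk(as.character(age0) %in% rownames(bundle$initial_population),
             "initial population missing age ", age0)
        start[i] <- cfg$start_year
        active[i] <- age0 < cfg$exit_age
        pop[i] <- if (active[i])
          bundle$initial_population[as.character(age0), s] else 0
      } else {
        .chk(as.character(b) %in% rownames(bundle$births),
             "births missing year ", b)
        start[i] <- b
        active[i] <- TRUE
        pop[i] <- bundle$births[as.character(b), s]
      }
    }
    data.frame(sex = s, birth_year = cohorts, start_year = start,
               population = pop, active = active)
  }))
  rownames(out) <- NULL
  out
}

#' Advance one cohort by one year under competing hazards
#'
#' Exact constant-hazard update: with total hazard `h = cvd + other`,
#' survivors are `population * exp(-h)` and the year's deaths
#' `population * (1 - exp(-h))` are allocated to causes in proportion
#' `cvd : other` (zero hazard gives zero deaths). If the cohort reaches
#' the exit age next year, all survivors age out and the next population
#' is zero.
#'
#' @param population Start-of-year stock (persons), vectorised.
#' @param cvd_hazard,other_hazard Cause-specific hazards per person-year
#'   (>= 0).
#' @param ages_out Logical: does the cohort turn `exit_age` next year?
#' @return List with `population` (next start-of-year stock), `cvd_deaths`,
#'   `other_deaths`, `aged_out`.
#' @export
step_cohort <- function(population, cvd_hazard, other_hazard,
                        ages_out = FALSE) {
  .chk(all(cvd_hazard >= 0) && all(other_hazard >= 0),
       "hazards must be non-negative")
  .chk(all(population >= 0), "population must be non-negative")
  h <- cvd_hazard + other_hazard
  survivors <- population * exp(-h)
  deaths <- population - survivors
  frac_cvd <- ifelse(h > 0, cvd_hazard / h, 0)
  cvd <- deaths * frac_cvd
  aged <- ifelse(ages_out, survivors, 0)
  list(population = ifelse(ages_out, 0, survivors),
       cvd_deaths = cvd,
       other_deaths = deaths - cvd,
       aged_out = aged)
}

#' Run the stock-flow simulation for one salt scenario
#'
#' Per calendar year and active cohort: the APC baseline hazard is split
#' into CVD and other-cause hazards, the CVD hazard is scaled by the
#' salt-effect multiplier for the difference between the assumed and
#' actual surfaces (period channel: current year and age; cohort channel:
#' intake at age 20), and the cohort stock is advanced with
#' [step_cohort()]. The full ledger of stocks and flows is returned.
#'
#' @param bundle A `salt_bundle`.
#' @param params An [apc_params()] (typically with calibrated `p`, `c`).
#' @param salt_actual The actual `salt_surface`.
#' @param salt_assumed The assumed (counterfactual) `salt_surface`; equal
#'   to `salt_actual` for the base run.
#' @param se A [salt_effect_params()].
#' @param cfg A [run_config()].
#' @param label Scenario label stored with the result.
#' @return A list of class `salt_sim`: `label`, `years`, `cohorts`, and
#'   per sex the matrices (cohort x year) `population` (start-of-year
#'   stock), `cvd_deaths`, `other_deaths`, `aged_out`, `other_hazard`, the
#'   logical `active` matrix, and `final_population` and `initial_stock`
#'   vectors for conservation accounting.
#' @export
run_model <- function(bundle, params, salt_actual, salt_assumed = salt_actual,
                      se = salt_effect_params(), cfg = bundle$config,
                      label = "base") {
  years <- cfg$start_year:cfg$end_year
  cohorts <- cfg$min_cohort_year:cfg$max_cohort_year
  ny <- length(years); nc <- length(cohorts)
  init <- init_cohorts(bundle, cfg)
  dn <- list(as.character(cohorts), as.character(years))

  sexes <- lapply(stats::setNames(SEXES, SEXES), function(s) {
    P <- Dc <- Do <- A <- Ho <- matrix(0, nc, ny, dimnames = dn)
    act <- matrix(FALSE, nc, ny, dimnames = dn)
    ini <- init[init$sex == s, ]
    initial_stock <- stats::setNames(ini$population, as.character(cohorts))
    initial_stock[!ini$active] <- 0
    ## stocks for cohorts alive at the start year; cohorts born later carry
    ## their birth count but are gated by their entry year below
    pop <- initial_stock

    m <- params$m1950[, s]
    pp <- params$p[[s]]; cc <- params$c[[s]]
    sa <- salt_actual$surface[[s]]; sb <- salt_assumed$surface[[s]]
    d20 <- salt_assumed$at20[[s]][as.character(cohorts)] -
           salt_actual$at20[[s]][as.character(cohorts)]
    .chk(!anyNA(d20), "salt at age 20 missing for some cohorts")

    for (j in seq_len(ny)) {
      t <- years[j]
      born <- ini$start_year == t & ini$birth_year >= cfg$start_year
      if (any(born)) pop[born] <- ini$population[born]
      entered <- ini$start_year <= t
      ages <- t - cohorts
      on <- entered & ages >= 0 & ages < cfg$exit_age & ini$active
      if (!any(on)) next
      a <- ages[on]
      .chk(as.character(t) %in% colnames(sa) &&
           as.character(t) %in% colnames(sb),
           "salt surface does not cover year ", t)
      h <- m[a + 1L] * pp ^ (t - params$period_reference_year) *
        cc ^ (cohorts[on] - params$cohort_reference_year)
      dp <- sb[a + 1L, as.character(t)] - sa[a + 1L, as.character(t)]
      mult <- salt_effect_multiplier(dp, d20[on], a, se)
      cs <- cause_specific_hazards(h, t, mult, params)
      last <- a == (cfg$exit_age - 1L)
      st <- step_cohort(pop[on], cs$cvd, cs$other, ages_out = last)
      P[on, j] <- pop[on]
      Dc[on, j] <- st$cvd_deaths
      Do[on, j] <- st$other_deaths
      A[on, j] <- st$aged_out
      Ho[on, j] <- cs$other
      act[on, j] <- TRUE
      pop[on] <- st$population
    }
    list(population = P, cvd_deaths = Dc, other_deaths = Do, aged_out = A,
         other_hazard = Ho, active = act,
         final_population = pop, initial_stock = initial_stock)
  })

  structure(list(label = label, years = years, cohorts = cohorts,
                 sexes = sexes),
            class = "salt_sim")
}

#' @export
print.salt_sim <- function(x, ...) {
  cat("Stock-flow simulation:", x$label, "\n")
  cat("  years:", min(x$years), "-", max(x$years),
      "| cohorts:", min(x$cohorts), "-", max(x$cohorts), "\n")
  for (s in names(x$sexes)) {
    r <- x$sexes[[s]]
    cat(sprintf("  %s: %.0f CVD deaths, %.0f other-cause deaths, %.0f aged out\n",
                s, sum(r$cvd_deaths), sum(r$other_deaths), sum(r$aged_out)))
  }
  invisible(x)
}

#' Annual CVD deaths summed over an age band
#'
#' @param result A `salt_sim`.
#' @param sex `"male"` or `"female"`.
#' @param age_range Inclusive age band over which deaths are counted
#'   (the reporting scope, ages 20-69).
#' @return Named numeric vector by year.
#' @export
annual_cvd_deaths <- function(result, sex, age_range = c(20L, 69L)) {
  r <- result$sexes[[sex]]
  ages <- outer(-result$cohorts, result$years, `+`)
  mask <- ages >= age_range[1] & ages <= age_range[2]
  stats::setNames(colSums(r$cvd_deaths * mask), as.character(result$years))
}
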