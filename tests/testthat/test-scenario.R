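test_that("excess tables difference scenario deaths against the base run", {
  scen <- test_scenarios()
  base <- scen$runs[["base"]]

  # scenario = base: all excess is zero
  self <- excess_table(base, base)
  expect_true(all(self$absolute_excess == 0))
  expect_true(all(self$relative_excess_pct[self$base_deaths > 0] == 0))

  # direct arithmetic on one counterfactual table
  e0 <- scen$excess[["0% effect"]]
  expect_equal(e0$absolute_excess, e0$scenario_deaths - e0$base_deaths,
               tolerance = 1e-12)
  ok <- e0$base_deaths > 0
  expect_equal(e0$relative_excess_pct[ok],
               100 * e0$absolute_excess[ok] / e0$base_deaths[ok],
               tolerance = 1e-12)

  # accumulated totals equal the sum of the annual column
  acc <- accumulated_excess(e0)
  for (s in c("male", "female"))
    expect_equal(acc$excess_deaths[acc$sex == s],
                 sum(e0$absolute_excess[e0$sex == s]), tolerance = 1e-12)

  # mismatched axes are rejected
  short <- base
  short$years <- base$years[-1]
  expect_error(excess_table(base, short), "axes")
})

test_that("a hand-built base/scenario pair gives 10 absolute and 10% relative", {
  mk <- function(deaths) {
    m <- matrix(deaths, 1, 1, dimnames = list("1930", "1980"))
    structure(list(label = "x", years = 1980L, cohorts = 1930L,
                   sexes = list(male = list(cvd_deaths = m),
                                female = list(cvd_deaths = m))),
              class = "salt_sim")
  }
  et <- excess_table(mk(100), mk(110))
  expect_equal(et$absolute_excess, c(10, 10), tolerance = 1e-12)
  expect_equal(et$relative_excess_pct, c(10, 10), tolerance = 1e-12)
})

test_that("annual CVD deaths are ordered monotonically in the effect fraction", {
  scen <- test_scenarios()
  for (s in c("male", "female")) {
    d <- sapply(scen$runs, function(r) annual_cvd_deaths(r, s))
    # columns ordered base (f=1) .. 0% effect: deaths must not decrease
    for (j in seq_len(ncol(d) - 1))
      expect_true(all(d[, j + 1] >= d[, j] - 1e-9),
                  label = sprintf("%s: %s vs %s", s, colnames(d)[j + 1],
                                  colnames(d)[j]))
  }
})

test_that("accumulated excess is near-linear in the retained effect fraction", {
  scen <- test_scenarios()
  acc <- scen$accumulated
  for (s in c("male", "female")) {
    a0 <- acc$excess_deaths[acc$sex == s & acc$scenario == "0% effect"]
    for (f in c(0.75, 0.5, 0.25)) {
      af <- acc$excess_deaths[acc$sex == s &
                                acc$scenario == sprintf("%d%% effect", 100 * f)]
      expect_lt(abs(af - (1 - f) * a0) / ((1 - f) * a0), 0.10)
    }
  }
})

test_that("other-cause hazards are identical across scenarios", {
  scen <- test_scenarios()
  base <- scen$runs[["base"]]
  for (r in scen$runs[-1]) for (s in c("male", "female"))
    expect_identical(r$sexes[[s]]$other_hazard, base$sexes[[s]]$other_hazard)
})

test_that("cohort mortality curves end at age 69 and skip empty cohorts", {
  base <- test_scenarios()$runs[["base"]]
  c1940 <- cohort_curve(base, 1940, "male")
  expect_equal(max(c1940$year), 2009)
  expect_equal(max(c1940$age), 69)
  c1910 <- cohort_curve(base, 1910, "male")
  expect_equal(max(c1910$year), 1979)
  # curves start at the simulation start for pre-1950 cohorts
  expect_equal(min(c1910$year), 1950)
  # the 1880 cohort contributes no person-time
  expect_equal(nrow(cohort_curve(base, 1880, "female")), 0L)
  expect_error(cohort_curve(base, 1850, "male"), "outside")
})

test_that("counterfactual scenarios raise cohort mortality, more so recently", {
  scen <- test_scenarios()
  base <- scen$runs[["base"]]
  f0 <- scen$runs[["0% effect"]]
  for (b in c(1910, 1940)) {
    rb <- cohort_curve(base, b, "male")
    r0 <- cohort_curve(f0, b, "male")
    adult <- rb$age >= 20
    expect_true(all(r0$rate_per_1000[adult] >= rb$rate_per_1000[adult]))
  }
  # relative difference at age 69 larger for the more recent cohort
  rel_diff <- function(b) {
    rb <- cohort_curve(base, b, "male"); r0 <- cohort_curve(f0, b, "male")
    i <- which.max(rb$age)
    (r0$rate_per_1000[i] - rb$rate_per_1000[i]) / rb$rate_per_1000[i]
  }
  expect_gt(rel_diff(1940), rel_diff(1910))
})

test_that("the command-line interface drives the whole pipeline", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "out")
  expect_message(saltapc_cli(c("synth", "--seed", "1", "--out-dir", dir)),
                 "synthetic bundle")
  saltapc_cli(c("impute-salt", "--in-dir", dir, "--out-dir", out))
  expect_true(file.exists(file.path(out, "salt_surface.csv")))
  expect_output(
    saltapc_cli(c("report", "--in-dir", dir, "--out-dir", out,
                  "--fractions", "1,0")),
    "accumulated excess")
  acc <- utils::read.csv(file.path(out, "accumulated_excess.csv"))
  expect_true(all(acc$excess_deaths > 0))
  expect_true(file.exists(file.path(out, "excess_by_year.csv")))
  expect_true(file.exists(file.path(out, "cohort_curves.csv")))
})
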