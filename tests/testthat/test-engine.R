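test_that("cohort initialisation maps stocks and births to the right years", {
  b <- test_bundle()
  init <- init_cohorts(b)
  male <- init[init$sex == "male", ]
  # pre-1950 cohorts start in 1950 with the initial stock at their age
  expect_equal(male$population[male$birth_year == 1930],
               unname(b$initial_population["20", "male"]))
  expect_equal(male$start_year[male$birth_year == 1930], 1950)
  # cohorts born during the simulation enter with their birth count
  expect_equal(male$population[male$birth_year == 1960],
               unname(b$births["1960", "male"]))
  expect_equal(male$start_year[male$birth_year == 1960], 1960)
  # the 1880 cohort is instantiated but inactive (age 70 at the start)
  expect_false(male$active[male$birth_year == 1880])
  expect_equal(nrow(male), 118L)
})

test_that("one annual step follows the constant-hazard competing-risks closed form", {
  st <- step_cohort(1000, 0.01, 0.01)
  expect_equal(st$population, 1000 * exp(-0.02), tolerance = 1e-12)
  expect_equal(st$cvd_deaths, 1000 * (1 - exp(-0.02)) / 2, tolerance = 1e-12)
  expect_equal(st$cvd_deaths, 9.9007, tolerance = 1e-4)
  expect_equal(st$other_deaths, st$cvd_deaths, tolerance = 1e-12)
  expect_equal(st$aged_out, 0)

  # zero hazard: everyone survives, no flows
  st0 <- step_cohort(500, 0, 0)
  expect_equal(st0$population, 500)
  expect_equal(st0$cvd_deaths + st0$other_deaths + st0$aged_out, 0)

  # exit-age step: survivors age out, stock empties
  st69 <- step_cohort(1000, 0.01, 0.01, ages_out = TRUE)
  expect_equal(st69$aged_out, 1000 * exp(-0.02), tolerance = 1e-12)
  expect_equal(st69$population, 0)

  expect_error(step_cohort(100, -0.01, 0.01), "non-negative")
})

test_that("a single-cohort two-year run matches the hand computation", {
  pop0 <- 1000; m0 <- 0.01; m1 <- 0.02; pr <- c(0.3, 0.4)
  b <- toy_bundle(pop0 = pop0, m0 = m0, m1 = m1, prop = pr)
  params <- apc_params(b$mortality_1950, p = 0.98, c = 0.999,
                       cvd_proportion = b$cvd_proportion)
  salt <- flat_salt(cohorts = 1950)
  sim <- run_model(b, params, salt, cfg = b$config, label = "toy")
  r <- sim$sexes$male

  # year 1950, age 0: hazard m0 * 0.98^0 * 0.999^70, CVD share 0.3
  h1 <- m0 * 0.999^70
  d1 <- pop0 * (1 - exp(-h1))
  expect_equal(unname(r$population[1, "1950"]), pop0)
  expect_equal(unname(r$cvd_deaths[1, "1950"]), d1 * pr[1], tolerance = 1e-12)
  expect_equal(unname(r$other_deaths[1, "1950"]), d1 * (1 - pr[1]),
               tolerance = 1e-12)

  # year 1951, age 1: hazard m1 * 0.98^1 * 0.999^70, CVD share 0.4
  pop1 <- pop0 * exp(-h1)
  h2 <- m1 * 0.98 * 0.999^70
  d2 <- pop1 * (1 - exp(-h2))
  expect_equal(unname(r$population[1, "1951"]), pop1, tolerance = 1e-12)
  expect_equal(unname(r$cvd_deaths[1, "1951"]), d2 * pr[2], tolerance = 1e-12)
  expect_equal(unname(r$final_population[1]), pop1 * exp(-h2),
               tolerance = 1e-12)
})

test_that("every cohort conserves persons to 1e-9 relative", {
  base <- test_scenarios()$runs[["base"]]
  for (s in c("male", "female")) {
    r <- base$sexes[[s]]
    inflow <- r$initial_stock
    outflow <- rowSums(r$cvd_deaths) + rowSums(r$other_deaths) +
      rowSums(r$aged_out) + r$final_population
    expect_equal(outflow, inflow, tolerance = 1e-9)
  }
})

test_that("no person-time is recorded at or beyond the exit age", {
  base <- test_scenarios()$runs[["base"]]
  ages <- outer(-base$cohorts, base$years, `+`)
  for (s in c("male", "female")) {
    r <- base$sexes[[s]]
    expect_true(all(r$population[ages >= 70 | ages < 0] == 0))
    expect_true(all(r$active[ages >= 70 | ages < 0] == FALSE))
    # aged-out flow only in the year a cohort is 69
    expect_true(all(r$aged_out[ages != 69] == 0))
  }
})

test_that("flows scale linearly with the population stocks", {
  b <- test_bundle()
  fit <- test_fit()
  b2 <- b
  b2$initial_population <- b$initial_population * 2
  b2$births <- b$births * 2
  s1 <- run_model(b, fit$params, fit$salt)
  s2 <- run_model(b2, fit$params, fit$salt)
  for (s in c("male", "female")) {
    expect_equal(s2$sexes[[s]]$cvd_deaths, 2 * s1$sexes[[s]]$cvd_deaths,
                 tolerance = 1e-12)
    expect_equal(s2$sexes[[s]]$aged_out, 2 * s1$sexes[[s]]$aged_out,
                 tolerance = 1e-12)
  }
})

test_that("a run with assumed = actual salt is the base run", {
  fit <- test_fit()
  base <- run_model(fit$bundle, fit$params, fit$salt, label = "base")
  same <- run_model(fit$bundle, fit$params, fit$salt, fit$salt,
                    label = "base")
  expect_identical(base$sexes, same$sexes)
})
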