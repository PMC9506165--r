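#' Simulation run configuration
#'
#' Collects the fixed frame of the simulation: the calendar window, the
#' cohort range (118 single-year birth cohorts), the adult and exit age
#' boundaries, the counterfactual effect fractions and the random seed.
#'
#' @param start_year First simulated calendar year.
#' @param end_year Last simulated calendar year.
#' @param min_cohort_year,max_cohort_year Earliest and latest birth cohorts;
#'   the defaults span 118 cohorts.
#' @param adult_age Age (completed years) from which salt differences act on
#'   CVD mortality.
#' @param exit_age Age at which survivors leave the modeled population (the
#'   70th birthday by default).
#' @param scenario_fractions Effect fractions `f` for the counterfactual
#'   scenarios; `f = 1` is the base run, `f = 0` freezes salt at its
#'   `start_year` level.
#' @param seed Integer seed used by any stochastic component.
#' @return A list of class `run_config`.
#' @export
run_config <- function(start_year = 1950L, end_year = 2017L,
                       min_cohort_year = 1880L, max_cohort_year = 1997L,
                       adult_age = 20L, exit_age = 70L,
                       scenario_fractions = c(1, 0.75, 0.5, 0.25, 0),
                       seed = 1L) {
  cfg <- list(start_year = as.integer(start_year),
              end_year = as.integer(end_year),
              min_cohort_year = as.integer(min_cohort_year),
              max_cohort_year = as.integer(max_cohort_year),
              adult_age = as.integer(adult_age),
              exit_age = as.integer(exit_age),
              scenario_fractions = as.numeric(scenario_fractions),
              seed = as.integer(seed))
  .chk(cfg$end_year >= cfg$start_year, "end_year must be >= start_year")
  .chk(cfg$exit_age > cfg$adult_age, "exit_age must exceed adult_age")
  .chk(all(cfg$scenario_fractions >= 0 & cfg$scenario_fractions <= 1),
       "scenario_fractions must lie in [0, 1]")
  n_cohorts <- cfg$max_cohort_year - cfg$min_cohort_year + 1L
  .chk(n_cohorts >= 1L, "cohort range is empty")
  cfg$n_cohorts <- n_cohorts
  class(cfg) <- "run_config"
  cfg
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Recognised keys override the corresponding [run_config()] defaults;
#' `scenario_fractions` may be a comma-separated list.
#'
#' @param path Path to the configuration file.
#' @return A `run_config` object.
#' @export
read_config <- function(path) {
  .chk(file.exists(path), "config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.*)$", lines))
  .chk(all(lengths(kv) == 3L), "malformed config line(s)")
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k == "scenario_fractions") {
      args[[k]] <- as.numeric(strsplit(vals[i], ",")[[1]])
    } else if (k %in% c("start_year", "end_year", "min_cohort_year",
                        "max_cohort_year", "adult_age", "exit_age", "seed")) {
      args[[k]] <- as.integer(vals[i])
    }
  }
  do.call(run_config, args)
}

.read_csv <- function(path, cols) {
  .chk(file.exists(path), "input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  .chk(length(missing) == 0L,
       basename(path), ": missing column(s) ", paste(missing, collapse = ", "))
  df
}

#' Assemble and validate a model input bundle
#'
#' The low-level constructor behind [read_inputs()] and [generate_bundle()].
#' All tables are validated: populations and rates must be non-negative,
#' rates below 1, proportions in \[0, 1\], and every age/year axis dense.
#'
#' @param initial_population Data frame `sex, age, population` for the start
#'   year (ages 0 to `exit_age`).
#' @param births Data frame `sex, year, births`.
#' @param mortality_1950 Data frame `sex, age, rate`: the start-year
#'   single-age mortality schedule (the age effect).
#' @param cvd_proportion Data frame `year, proportion`: CVD share of total
#'   mortality per year.
#' @param observed_mortality Data frame `sex, year, age, rate`: the observed
#'   mortality-rate surface used for calibration.
#' @param salt_overall Data frame `sex, year, grams_per_day` of overall mean
#'   salt intake (use `sex = "all"` for a combined series).
#' @param salt_groups Data frame
#'   `sex, year, age_group_start, age_group_end, grams_per_day` of mean salt
#'   intake by 10-year age group.
#' @param config A [run_config()].
#' @return A list of class `salt_bundle` with matrix/vector representations
#'   of every table (ages and years as dimnames).
#' @export
salt_bundle <- function(initial_population, births, mortality_1950,
                        cvd_proportion, observed_mortality,
                        salt_overall, salt_groups, config = run_config()) {
  years <- config$start_year:config$end_year
  init_ages <- 0:config$exit_age
  model_ages <- 0:(config$exit_age - 1L)

  .chk(all(initial_population$population >= 0), "negative initial population")
  .chk(all(births$births >= 0), "negative birth count")
  .chk(all(mortality_1950$rate >= 0 & mortality_1950$rate < 1),
       "1950 mortality rates must lie in [0, 1)")
  .chk(all(observed_mortality$rate >= 0 & observed_mortality$rate < 1),
       "observed mortality rates must lie in [0, 1)")
  .chk(all(cvd_proportion$proportion >= 0 & cvd_proportion$proportion <= 1),
       "cvd proportion must lie in [0, 1]")
  .chk(all(salt_overall$grams_per_day > 0), "salt intake must be positive")
  .chk(all(salt_groups$grams_per_day > 0), "salt intake must be positive")

  birth_years <- .dense_axis(births$year, "births year")
  .dense_axis(cvd_proportion$year, "cvd_proportion year")

  init <- .num_matrix(initial_population, "age", "population", init_ages,
                      "initial_population")
  b <- .num_matrix(births, "year", "births", birth_years, "births")
  m1950 <- .num_matrix(mortality_1950, "age", "rate", model_ages,
                       "mortality_1950")

  prop <- stats::setNames(cvd_proportion$proportion,
                          as.character(cvd_proportion$year))
  .chk(all(as.character(years) %in% names(prop)),
       "cvd_proportion must cover every simulated year")
  prop <- prop[as.character(years)]

  obs <- lapply(stats::setNames(SEXES, SEXES), function(s) {
    d <- observed_mortality[observed_mortality$sex == s, , drop = FALSE]
    .chk(nrow(d) > 0, "observed_mortality has no rows for sex '", s, "'")
    .dense_axis(d$year, paste0("observed_mortality (", s, ") year"))
    m <- matrix(NA_real_, length(model_ages), length(years),
                dimnames = list(as.character(model_ages), as.character(years)))
    idx <- cbind(match(d$age, model_ages), match(d$year, years))
    keep <- stats::complete.cases(idx)
    m[idx[keep, , drop = FALSE]] <- d$rate[keep]
    .chk(!anyNA(m), "observed_mortality (", s, ") has missing age x year cells")
    m
  })

  structure(list(initial_population = init,
                 births = b,
                 mortality_1950 = m1950,
                 cvd_proportion = prop,
                 observed_mortality = obs,
                 salt_overall = salt_overall[c("sex", "year", "grams_per_day")],
                 salt_groups = salt_groups[c("sex", "year", "age_group_start",
                                             "age_group_end", "grams_per_day")],
                 config = config),
            class = "salt_bundle")
}

#' Read a model input bundle from a directory of CSV files
#'
#' Expects `population_1950.csv` (sex,age,population), `births.csv`
#' (sex,year,births), `mortality_1950.csv` (sex,age,rate),
#' `cvd_proportion.csv` (year,proportion), `observed_mortality.csv`
#' (sex,year,age,rate), `salt_overall.csv` (sex,year,grams_per_day) and
#' `salt_by_group.csv` (sex,year,age_group_start,age_group_end,
#' grams_per_day). Missing cells are an error, never imputed.
#'
#' @param dir Directory containing the CSV files.
#' @param config A [run_config()].
#' @return A `salt_bundle`.
#' @export
read_inputs <- function(dir, config = run_config()) {
  salt_bundle(
    initial_population = .read_csv(file.path(dir, "population_1950.csv"),
                                   c("sex", "age", "population")),
    births = .read_csv(file.path(dir, "births.csv"),
                       c("sex", "year", "births")),
    mortality_1950 = .read_csv(file.path(dir, "mortality_1950.csv"),
                               c("sex", "age", "rate")),
    cvd_proportion = .read_csv(file.path(dir, "cvd_proportion.csv"),
                               c("year", "proportion")),
    observed_mortality = .read_csv(file.path(dir, "observed_mortality.csv"),
                                   c("sex", "year", "age", "rate")),
    salt_overall = .read_csv(file.path(dir, "salt_overall.csv"),
                             c("sex", "year", "grams_per_day")),
    salt_groups = .read_csv(file.path(dir, "salt_by_group.csv"),
                            c("sex", "year", "age_group_start",
                              "age_group_end", "grams_per_day")),
    config = config)
}

#' Write a model input bundle to CSV files
#'
#' Inverse of [read_inputs()]: writes the seven input CSVs into `dir`.
#'
#' @param bundle A `salt_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "salt_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
  }
  mat_long <- function(m, row_var, value_var) {
    do.call(rbind, lapply(SEXES, function(s) {
      d <- data.frame(sex = s, row = as.integer(rownames(m)), value = m[, s])
      names(d)[2:3] <- c(row_var, value_var)
      d
    }))
  }
  obs <- do.call(rbind, lapply(SEXES, function(s) {
    m <- bundle$observed_mortality[[s]]
    expand <- expand.grid(age = as.integer(rownames(m)),
                          year = as.integer(colnames(m)))
    data.frame(sex = s, year = expand$year, age = expand$age,
               rate = as.vector(m))
  }))
  paths <- c(
    w(mat_long(bundle$initial_population, "age", "population"),
      "population_1950.csv"),
    w(mat_long(bundle$births, "year", "births"), "births.csv"),
    w(mat_long(bundle$mortality_1950, "age", "rate"), "mortality_1950.csv"),
    w(data.frame(year = as.integer(names(bundle$cvd_proportion)),
                 proportion = unname(bundle$cvd_proportion)),
      "cvd_proportion.csv"),
    w(obs, "observed_mortality.csv"),
    w(bundle$salt_overall, "salt_overall.csv"),
    w(bundle$salt_groups, "salt_by_group.csv"))
  invisible(paths)
}

#' @export
print.salt_bundle <- function(x, ...) {
  cat("Model input bundle\n")
  cat("  years:", x$config$start_year, "-", x$config$end_year, "\n")
  cat("  cohorts:", x$config$min_cohort_year, "-", x$config$max_cohort_year,
      sprintf("(%d)", x$config$n_cohorts), "\n")
  cat("  initial population (both sexes):",
      format(round(sum(x$initial_population)), big.mark = ","), "\n")
  cat("  salt survey years: overall",
      paste(range(x$salt_overall$year), collapse = "-"), "| by group",
      paste(range(x$salt_groups$year), collapse = "-"), "\n")
  invisible(x)
}

#' Convert a simulation result to a long data frame
#'
#' One row per sex x year x cohort that was alive (active) at the start of
#' the year, with the start-of-year stock and the year's flows.
#'
#' @param x A `salt_sim` object from [run_model()].
#' @param ... Unused.
#' @return A data frame with columns `scenario, sex, year, cohort, age,
#'   population, cvd_deaths, other_deaths, aged_out`.
#' @export
as.data.frame.salt_sim <- function(x, ...) {
  out <- lapply(SEXES, function(s) {
    r <- x$sexes[[s]]
    act <- which(r$active, arr.ind = TRUE)
    if (nrow(act) == 0L) return(NULL)
    cohort <- x$cohorts[act[, 1L]]
    year <- x$years[act[, 2L]]
    d <- data.frame(scenario = x$label, sex = s, year = year, cohort = cohort,
                    age = year - cohort,
                    population = r$population[act],
                    cvd_deaths = r$cvd_deaths[act],
                    other_deaths = r$other_deaths[act],
                    aged_out = r$aged_out[act])
    d[order(d$year, d$cohort), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(scenario = character(), sex = character(),
                      year = integer(), cohort = integer(), age = integer(),
                      population = numeric(), cvd_deaths = numeric(),
                      other_deaths = numeric(), aged_out = numeric())
  rownames(out) <- NULL
  out
}

#' Write a simulation result to a tidy CSV
#'
#' @param result A `salt_sim` object.
#' @param path Output file path.
#' @return Invisibly, the long data frame written.
#' @export
write_result <- function(result, path) {
  df <- as.data.frame(result)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read back a simulation result CSV
#'
#' @param path Path written by [write_result()].
#' @return The long-format data frame.
#' @export
read_result <- function(path) {
  .read_csv(path, c("scenario", "sex", "year", "cohort", "age", "population",
                    "cvd_deaths", "other_deaths", "aged_out"))
}
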