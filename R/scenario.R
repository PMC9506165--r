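.scenario_label <- function(f)
  if (f == 1) "base" else sprintf("%d%% effect", round(100 * f))

#' Run base and counterfactual salt scenarios
#'
#' One full stock-flow run per effect fraction, all sharing the calibrated
#' coefficients and inputs. The assumed salt surface for fraction `f`
#' retains `f` of the actual post-anchor change ([counterfactual_salt()]);
#' `f = 1` is the base run.
#'
#' @param fit A `salt_apc` fit.
#' @param fractions Effect fractions to run (always includes 1 for the
#'   base run).
#' @param anchor_year Anchor of the counterfactual surfaces.
#' @return Named list of `salt_sim` results, keyed by scenario label.
#' @export
run_scenarios <- function(fit, fractions = fit$bundle$config$scenario_fractions,
                          anchor_year = fit$bundle$config$start_year) {
  stopifnot(inherits(fit, "salt_apc"))
  fractions <- sort(unique(c(1, fractions)), decreasing = TRUE)
  runs <- lapply(fractions, function(f) {
    assumed <- counterfactual_salt(fit$salt, f, anchor_year)
    run_model(fit$bundle, fit$params, fit$salt, assumed, se = fit$se,
              label = .scenario_label(f))
  })
  names(runs) <- vapply(fractions, .scenario_label, "")
  attr(runs, "fractions") <- fractions
  runs
}

#' Annual and accumulated excess CVD mortality versus the base run
#'
#' Per sex and year, CVD deaths at ages 20-69 are summed over cohorts;
#' absolute excess is `scenario - base` and relative excess is
#' `100 * absolute / base` (where base > 0). The accumulated excess is
#' the sum of the annual absolute column.
#'
#' @param base The base-run `salt_sim`.
#' @param scenario A counterfactual `salt_sim` on the same axes.
#' @param age_range Reporting age band.
#' @return Data frame of class `excess_table`: `sex, year, scenario,
#'   base_deaths, scenario_deaths, absolute_excess, relative_excess_pct`,
#'   with the per-sex accumulated totals as attribute `"accumulated"`.
#' @export
excess_table <- function(base, scenario, age_range = c(20L, 69L)) {
  .chk(identical(base$years, scenario$years) &&
       identical(base$cohorts, scenario$cohorts),
       "base and scenario runs are on different axes")
  out <- do.call(rbind, lapply(SEXES, function(s) {
    b <- annual_cvd_deaths(base, s, age_range)
    x <- annual_cvd_deaths(scenario, s, age_range)
    data.frame(sex = s, year = base$years, scenario = scenario$label,
               base_deaths = unname(b), scenario_deaths = unname(x),
               absolute_excess = unname(x - b),
               relative_excess_pct = unname(ifelse(b > 0, 100 * (x - b) / b,
                                                   NA_real_)))
  }))
  rownames(out) <- NULL
  acc <- stats::aggregate(absolute_excess ~ sex, out, sum)
  names(acc)[2] <- "excess_deaths"
  acc$scenario <- scenario$label
  attr(out, "accumulated") <- acc[c("sex", "scenario", "excess_deaths")]
  class(out) <- c("excess_table", "data.frame")
  out
}

#' Accumulated excess CVD deaths per sex and scenario
#'
#' @param x An `excess_table`, a list of them, or a `salt_scenarios`
#'   object.
#' @return Data frame `sex, scenario, excess_deaths`.
#' @export
accumulated_excess <- function(x) {
  if (inherits(x, "salt_scenarios")) x <- x$excess
  if (inherits(x, "excess_table")) x <- list(x)
  out <- do.call(rbind, lapply(x, function(e) attr(e, "accumulated")))
  rownames(out) <- NULL
  out
}

#' CVD mortality-rate curve for one birth cohort
#'
#' The cohort's CVD deaths divided by its start-of-year population, per
#' 1000 person-years, over its active calendar years. The curve ends in
#' the year the cohort is aged 69 (e.g. 2009 for the 1940 cohort).
#'
#' @param result A `salt_sim`.
#' @param birth_year Cohort birth year.
#' @param sex `"male"` or `"female"`.
#' @return Data frame `year, age, rate_per_1000` (empty for a cohort with
#'   no person-time).
#' @export
cohort_curve <- function(result, birth_year, sex) {
  .chk(birth_year %in% result$cohorts, "cohort outside the simulated range")
  r <- result$sexes[[sex]]
  i <- match(birth_year, result$cohorts)
  on <- r$active[i, ] & r$population[i, ] > 0
  data.frame(year = result$years[on],
             age = result$years[on] - birth_year,
             rate_per_1000 = 1000 * r$cvd_deaths[i, on] / r$population[i, on])
}

#' Simulate counterfactual salt scenarios from a fitted model
#'
#' Runs the base and counterfactual scenarios and computes the excess
#' analytics. The model is deterministic, so `nsim` and `seed` are
#' accepted for generic compatibility but a single replicate is returned.
#'
#' @param object A `salt_apc` fit.
#' @param nsim,seed Ignored (deterministic model).
#' @param fractions Effect fractions; defaults to the bundle's
#'   configuration (1, 0.75, 0.5, 0.25, 0).
#' @param anchor_year Counterfactual anchor year.
#' @param age_range Reporting age band for excess tables.
#' @param ... Unused.
#' @return An object of class `salt_scenarios`: `runs` (per-scenario
#'   `salt_sim`), `excess` (per counterfactual scenario), `accumulated`,
#'   and `fractions`.
#' @export
simulate.salt_apc <- function(object, nsim = 1, seed = NULL,
                              fractions = object$bundle$config$scenario_fractions,
                              anchor_year = object$bundle$config$start_year,
                              age_range = c(20L, 69L), ...) {
  runs <- run_scenarios(object, fractions, anchor_year)
  base <- runs[["base"]]
  cf <- runs[names(runs) != "base"]
  excess <- lapply(cf, function(r) excess_table(base, r, age_range))
  structure(list(runs = runs, excess = excess,
                 accumulated = accumulated_excess(excess),
                 fractions = attr(runs, "fractions")),
            class = "salt_scenarios")
}

#' @export
print.salt_scenarios <- function(x, ...) {
  cat("Salt counterfactual scenarios\n")
  cat("  effect fractions:", paste(x$fractions, collapse = ", "), "\n")
  if (nrow(x$accumulated %||% data.frame()) > 0) {
    cat("  accumulated excess CVD deaths (ages 20-69):\n")
    acc <- x$accumulated
    acc$excess_deaths <- round(acc$excess_deaths)
    print.data.frame(acc, row.names = FALSE)
  }
  invisible(x)
}

#' Plot annual excess CVD mortality by scenario
#'
#' Absolute (persons/year) or relative (%) excess versus the base run,
#' one panel per sex, one line per counterfactual scenario.
#'
#' @param x A `salt_scenarios` object.
#' @param type `"absolute"` or `"relative"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.salt_scenarios <- function(x, type = c("absolute", "relative"), ...) {
  type <- match.arg(type)
  col <- if (type == "absolute") "absolute_excess" else "relative_excess_pct"
  ylab <- if (type == "absolute") "excess CVD deaths (persons/year)"
          else "relative excess CVD mortality (%)"
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (s in SEXES) {
    series <- lapply(x$excess, function(e) e[e$sex == s, col])
    years <- unique(x$excess[[1]]$year)
    graphics::matplot(years, do.call(cbind, series), type = "l", lty = 1,
                      xlab = "year", ylab = ylab, main = s, ...)
    graphics::legend("topleft", legend = names(x$excess),
                     col = seq_along(series), lty = 1, cex = 0.7, bty = "n")
  }
  invisible(x)
}
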