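#' Fit the salt-APC cardiovascular mortality model
#'
#' The package's main entry point. Given an input bundle (read with
#' [read_inputs()] or generated with [generate_bundle()]), it
#' reconstructs the salt-exposure surface from the survey tables (unless
#' one is supplied), calibrates the period and cohort coefficients per sex
#' against the observed mortality surface, and returns a fitted model
#' object. Counterfactual scenarios are then run with
#' [simulate.salt_apc()].
#'
#' @param bundle A `salt_bundle`.
#' @param salt Optional pre-built `salt_surface`; imputed from the
#'   bundle's survey tables when `NULL`.
#' @param spec A [calibration_spec()].
#' @param se A [salt_effect_params()].
#' @param impute_cfg An [imputation_config()] used when `salt` is `NULL`.
#' @return An object of class `salt_apc` with components `calibration`
#'   (the [calibrate()] table), `params` (the fitted [apc_params()]),
#'   `salt`, `bundle`, `se`, `spec` and `call`. Methods: `print`,
#'   `summary`, `coef`, `fitted`, `predict`, `residuals`, `simulate`,
#'   `plot`.
#' @examples
#' bundle <- generate_bundle(synth_config(seed = 1))
#' fit <- salt_apc(bundle)
#' coef(fit)
#' scen <- simulate(fit, fractions = c(1, 0.5, 0))
#' accumulated_excess(scen)
#' @export
salt_apc <- function(bundle, salt = NULL, spec = calibration_spec(),
                     se = salt_effect_params(),
                     impute_cfg = imputation_config()) {
  stopifnot(inherits(bundle, "salt_bundle"))
  if (is.null(salt))
    salt <- impute_salt(bundle$salt_overall, bundle$salt_groups,
                        cfg = impute_cfg,
                        cohorts = bundle$config$min_cohort_year:
                          bundle$config$max_cohort_year,
                        end_year = bundle$config$end_year)
  cal <- calibrate(bundle, spec = spec)
  params <- apc_params(bundle$mortality_1950,
                       p = stats::setNames(cal$p, cal$sex),
                       c = stats::setNames(cal$c, cal$sex),
                       cvd_proportion = bundle$cvd_proportion)
  structure(list(calibration = cal, params = params, salt = salt,
                 bundle = bundle, se = se, spec = spec,
                 call = match.call()),
            class = "salt_apc")
}

#' @export
coef.salt_apc <- function(object, ...) {
  m <- cbind(p = object$calibration$p, c = object$calibration$c)
  rownames(m) <- object$calibration$sex
  m
}

#' Fitted total mortality-rate surfaces
#'
#' @param object A `salt_apc` fit.
#' @param ... Unused.
#' @return Per-sex list of age x year rate matrices at the calibrated
#'   coefficients (base run, salt multiplier 1).
#' @export
fitted.salt_apc <- function(object, ...) {
  p <- object$params
  lapply(stats::setNames(SEXES, SEXES), function(s)
    model_rate_surface(p$m1950[, s], p$p[[s]], p$c[[s]],
                       ages = as.integer(rownames(p$m1950)),
                       years = object$bundle$config$start_year:
                         object$bundle$config$end_year))
}

#' Log-scale calibration residuals
#'
#' @param object A `salt_apc` fit.
#' @param ... Unused.
#' @return Per-sex list of matrices `log(observed) - log(fitted)`.
#' @export
residuals.salt_apc <- function(object, ...) {
  fit <- fitted(object)
  lapply(stats::setNames(SEXES, SEXES), function(s)
    log(object$bundle$observed_mortality[[s]]) - log(fit[[s]]))
}

#' Predict mortality rates from the fitted APC model
#'
#' @param object A `salt_apc` fit.
#' @param ages,years Grid to evaluate (defaults to the modeled grid).
#' @param type `"total"` for the all-cause rate, `"cvd"` for the CVD
#'   component (total times the year's CVD proportion, base run).
#' @param ... Unused.
#' @return Long data frame `sex, year, age, rate`.
#' @export
predict.salt_apc <- function(object, ages = NULL, years = NULL,
                             type = c("total", "cvd"), ...) {
  type <- match.arg(type)
  p <- object$params
  ages <- ages %||% as.integer(rownames(p$m1950))
  years <- years %||%
    object$bundle$config$start_year:object$bundle$config$end_year
  out <- do.call(rbind, lapply(SEXES, function(s) {
    m <- model_rate_surface(p$m1950[, s], p$p[[s]], p$c[[s]], ages, years)
    if (type == "cvd") {
      .chk(all(as.character(years) %in% names(p$cvd_proportion)),
           "year outside the cvd_proportion table")
      m <- sweep(m, 2, p$cvd_proportion[as.character(years)], `*`)
    }
    g <- expand.grid(age = ages, year = years)
    data.frame(sex = s, year = g$year, age = g$age, rate = as.vector(m))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.salt_apc <- function(x, digits = 6, ...) {
  cat("Salt-APC cardiovascular mortality model\n")
  cat("  years:", x$bundle$config$start_year, "-", x$bundle$config$end_year,
      "| cohorts:", x$bundle$config$min_cohort_year, "-",
      x$bundle$config$max_cohort_year, "\n")
  cat("  salt effect:", x$se$percent_per_unit, "% per",
      x$se$grams_per_unit, "g/day, period:cohort",
      x$se$period_weight, ":", x$se$cohort_weight,
      ", from age", x$se$min_effect_age, "\n")
  cat("  calibrated coefficients:\n")
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
summary.salt_apc <- function(object, ...) {
  res <- residuals(object)
  s <- list(coefficients = coef(object),
            calibration = object$calibration,
            residual_quartiles = t(vapply(res, stats::quantile,
                                          numeric(5))),
            rmse = vapply(res, function(r) sqrt(mean(r^2)), numeric(1)))
  class(s) <- "summary.salt_apc"
  s
}

#' @export
print.summary.salt_apc <- function(x, digits = 6, ...) {
  cat("Salt-APC model: calibration summary\n\nCoefficients:\n")
  print(round(x$coefficients, digits))
  cat("\nLog-rate residual quartiles:\n")
  print(round(x$residual_quartiles, 4))
  cat("\nLog-rate RMSE:", paste(names(x$rmse),
                                signif(x$rmse, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Diagnostic plot of observed versus fitted mortality rates
#'
#' Log-scale observed (points) and fitted (lines) rates by year at a few
#' ages, one panel per sex.
#'
#' @param x A `salt_apc` fit.
#' @param ages Ages to display.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.salt_apc <- function(x, ages = c(30, 50, 69), ...) {
  fit <- fitted(x)
  years <- as.integer(colnames(fit[[1]]))
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (s in SEXES) {
    obs <- x$bundle$observed_mortality[[s]][as.character(ages), , drop = FALSE]
    graphics::matplot(years, t(log10(obs)), pch = 1, cex = 0.5,
                      xlab = "year", ylab = "log10 mortality rate",
                      main = s, ...)
    graphics::matlines(years,
                       t(log10(fit[[s]][as.character(ages), , drop = FALSE])),
                       lty = 1)
    graphics::legend("bottomleft", legend = paste("age", ages),
                     col = seq_along(ages), lty = 1, cex = 0.7, bty = "n")
  }
  invisible(x)
}
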