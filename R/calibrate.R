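#' Calibration specification
#'
#' Defaults for fitting the period and cohort coefficients: sum of squared
#' differences of log rates over the full age x year grid, a Nelder-Mead
#' simplex started at the neutral point (1, 1) with box bounds enforced by
#' penalty, and a restart from the best point to polish convergence.
#'
#' @param age_range Inclusive single-age range of the calibration grid.
#' @param year_range Inclusive year range of the grid.
#' @param scale `"log"` (default) compares log rates; `"linear"` compares
#'   rates directly.
#' @param init Initial `(p, c)`.
#' @param lower,upper Box bounds on both coefficients.
#' @param tol Convergence tolerance on the loss.
#' @param maxit Iteration cap per simplex run.
#' @return A list of class `calibration_spec`.
#' @export
calibration_spec <- function(age_range = c(0L, 69L),
                             year_range = c(1950L, 2017L),
                             scale = c("log", "linear"),
                             init = c(p = 1, c = 1),
                             lower = 0.8, upper = 1.2,
                             tol = 1e-10, maxit = 2000L) {
  .chk(all(init >= lower & init <= upper), "bounds must contain the initial point")
  structure(list(age_range = as.integer(age_range),
                 year_range = as.integer(year_range),
                 scale = match.arg(scale),
                 init = init, lower = lower, upper = upper,
                 tol = tol, maxit = as.integer(maxit)),
            class = "calibration_spec")
}

#' Model mortality-rate surface for one sex
#'
#' The APC product evaluated on a full age x year grid (base run, salt
#' multiplier 1): `m1950(a) * p^(t - 1950) * c^((t - a) - reference)`.
#'
#' @param m1950_sex Named numeric vector of 1950 rates by single age.
#' @param p,c Period and cohort coefficients.
#' @param ages,years Grid axes.
#' @param cohort_reference_year Birth year with cohort effect 1.
#' @param period_reference_year Year with period effect 1.
#' @return Matrix ages x years of rates.
#' @export
model_rate_surface <- function(m1950_sex, p, c, ages = 0:69,
                               years = 1950:2017,
                               cohort_reference_year = 1880L,
                               period_reference_year = 1950L) {
  .chk(all(as.character(ages) %in% names(m1950_sex)),
       "age outside the m1950 table")
  ep <- matrix(rep(years - period_reference_year, each = length(ages)),
               length(ages), length(years))
  ec <- outer(-ages, years - cohort_reference_year, `+`)
  m <- m1950_sex[as.character(ages)] * p ^ ep * c ^ ec
  dimnames(m) <- list(as.character(ages), as.character(years))
  m
}

#' Calibration loss for a coefficient pair
#'
#' Sum over the calibration grid of squared differences between model and
#' observed rates, on the log scale by default (mortality spans orders of
#' magnitude across age; log loss weights young ages fairly).
#'
#' @param p,c Coefficients to evaluate.
#' @param observed Matrix ages x years of observed rates (> 0 on the log
#'   scale).
#' @param m1950_sex Named numeric vector of 1950 rates by single age.
#' @param spec A [calibration_spec()].
#' @param cohort_reference_year,period_reference_year Model references.
#' @return Scalar loss, >= 0.
#' @export
apc_loss <- function(p, c, observed, m1950_sex, spec = calibration_spec(),
                     cohort_reference_year = 1880L,
                     period_reference_year = 1950L) {
  ages <- spec$age_range[1]:spec$age_range[2]
  years <- spec$year_range[1]:spec$year_range[2]
  .chk(all(as.character(ages) %in% rownames(observed)) &&
       all(as.character(years) %in% colnames(observed)),
       "observed surface does not cover the calibration grid")
  obs <- observed[as.character(ages), as.character(years)]
  mod <- model_rate_surface(m1950_sex, p, c, ages, years,
                            cohort_reference_year, period_reference_year)
  if (spec$scale == "log") {
    .chk(all(obs > 0), "observed rates must be positive for the log loss")
    sum((log(mod) - log(obs))^2)
  } else {
    sum((mod - obs)^2)
  }
}

.calibrate_sex <- function(observed, m1950_sex, spec,
                           cohort_reference_year, period_reference_year) {
  pen_obj <- function(par) {
    lo <- spec$lower; hi <- spec$upper
    excess <- sum(pmax(lo - par, 0) + pmax(par - hi, 0))
    par <- pmin(pmax(par, lo), hi)
    apc_loss(par[1], par[2], observed, m1950_sex, spec,
             cohort_reference_year, period_reference_year) + 1e6 * excess^2
  }
  ctrl <- list(maxit = spec$maxit, reltol = 1e-14)
  fit <- stats::optim(spec$init, pen_obj, method = "Nelder-Mead",
                      control = ctrl)
  ## restart the simplex at the best point: Nelder-Mead can stall with a
  ## collapsed simplex; a fresh simplex polishes the optimum
  refit <- stats::optim(fit$par, pen_obj, method = "Nelder-Mead",
                        control = ctrl)
  iterations <- unname(fit$counts[1]) + unname(refit$counts[1])
  ## convergence is judged on the primary run; the restart only polishes
  ## the optimum (its simplex may legitimately collapse there, code 10)
  converged <- fit$convergence == 0
  if (refit$value < fit$value) fit <- refit
  par <- pmin(pmax(fit$par, spec$lower), spec$upper)
  list(p = unname(par[1]), c = unname(par[2]), loss = fit$value,
       iterations = iterations, converged = converged)
}

#' Fit the period and cohort coefficients to an observed mortality surface
#'
#' Independent per-sex fits minimising [apc_loss()] from the neutral
#' initial point. Non-convergence within the iteration cap is flagged and
#' the best point returned.
#'
#' @param observed Per-sex list of observed rate matrices (ages x years),
#'   or a `salt_bundle` (its `observed_mortality` is used).
#' @param m1950 Matrix ages x sex of 1950 rates (taken from the bundle if
#'   one is supplied).
#' @param spec A [calibration_spec()].
#' @param cohort_reference_year,period_reference_year Model references.
#' @return A data frame of class `salt_calibration`:
#'   `sex, p, c, loss, iterations, converged`.
#' @export
calibrate <- function(observed, m1950 = NULL, spec = calibration_spec(),
                      cohort_reference_year = 1880L,
                      period_reference_year = 1950L) {
  if (inherits(observed, "salt_bundle")) {
    m1950 <- observed$mortality_1950
    observed <- observed$observed_mortality
  }
  .chk(!is.null(m1950), "m1950 table required")
  out <- do.call(rbind, lapply(SEXES, function(s) {
    fit <- .calibrate_sex(observed[[s]], m1950[, s], spec,
                          cohort_reference_year, period_reference_year)
    data.frame(sex = s, p = fit$p, c = fit$c, loss = fit$loss,
               iterations = fit$iterations, converged = fit$converged)
  }))
  rownames(out) <- NULL
  class(out) <- c("salt_calibration", "data.frame")
  out
}

#' @export
print.salt_calibration <- function(x, digits = 6, ...) {
  cat("APC coefficient calibration (Nelder-Mead, log-rate least squares)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
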