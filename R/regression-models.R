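#' Fit the utility-by-MMD linear model
#'
#' Ordinary least squares of observed utility on monthly migraine days.
#' The slope is reported as a positive decrement magnitude (utility lost
#' per additional MMD), matching the convention used throughout the
#' model.
#'
#' @param records data frame with columns `mmd` and `utility_observed`
#'   (e.g. from [generate_trial()]).
#' @return a `fitted_linear_model`: list with `intercept`, `slope`
#'   (positive decrement), `intercept_se`, `slope_se`, `residual_sd`,
#'   `n_obs` and the 2x2 coefficient `covariance` (on the
#'   intercept/decrement scale).
#' @export
fit_utility_model <- function(records) {
  fit_decrement_model(records$utility_observed, records$mmd,
                      what = "utility")
}

#' Fit the absenteeism and presenteeism work-loss models
#'
#' Linear regressions of MIDAS absent days and presenteeism days (both
#' per 3 months) on MMD.  Predictions are floored at zero downstream.
#'
#' @param records data frame with columns `mmd`, `midas_days_absent` and
#'   `presenteeism_days`.
#' @return list with components `absenteeism` and `presenteeism`, each a
#'   `fitted_linear_model` whose `slope` is signed (days gained per MMD).
#' @export
fit_work_loss_models <- function(records) {
  list(
    absenteeism = fit_slope_model(records$midas_days_absent, records$mmd,
                                  what = "absenteeism"),
    presenteeism = fit_slope_model(records$presenteeism_days, records$mmd,
                                   what = "presenteeism"))
}

fit_lm_core <- function(y, x, what) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3)
    stop(what, " model needs at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0)
    stop(what, " model: singular design (constant MMD column)",
         call. = FALSE)
  fit <- stats::lm(y ~ x)
  # noiseless calibration data interpolates exactly; the "essentially
  # perfect fit" warning is expected there, not actionable
  sm <- suppressWarnings(summary(fit))
  list(fit = fit, sm = sm, V = suppressWarnings(stats::vcov(fit)),
       n = length(y))
}

# slope reported as a positive decrement magnitude; covariance re-signed
fit_decrement_model <- function(y, x, what) {
  f <- fit_lm_core(y, x, what)
  co <- f$sm$coefficients
  V <- f$V
  S <- diag(c(1, -1))
  structure(list(
    intercept = unname(co[1, 1]),
    slope = -unname(co[2, 1]),
    intercept_se = unname(co[1, 2]),
    slope_se = unname(co[2, 2]),
    residual_sd = f$sm$sigma,
    n_obs = f$n,
    covariance = S %*% V %*% S,
    slope_is_decrement = TRUE),
    class = "fitted_linear_model")
}

fit_slope_model <- function(y, x, what) {
  f <- fit_lm_core(y, x, what)
  co <- f$sm$coefficients
  # work-loss outcomes are overdispersed counts whose variance grows with
  # the mean; heteroskedasticity-consistent (HC1) errors keep the
  # coefficient CIs honest where classical OLS errors undercover
  V <- suppressWarnings(sandwich::vcovHC(f$fit, type = "HC1"))
  structure(list(
    intercept = unname(co[1, 1]),
    slope = unname(co[2, 1]),
    intercept_se = sqrt(V[1, 1]),
    slope_se = sqrt(V[2, 2]),
    residual_sd = f$sm$sigma,
    n_obs = f$n,
    covariance = V,
    slope_is_decrement = FALSE),
    class = "fitted_linear_model")
}

#' @export
print.fitted_linear_model <- function(x, ...) {
  cat(sprintf("<fitted_linear_model> n = %d\n", x$n_obs))
  cat(sprintf("  intercept %.5f (se %.5f)\n", x$intercept, x$intercept_se))
  lab <- if (isTRUE(x$slope_is_decrement)) "decrement per MMD" else
    "slope per MMD"
  cat(sprintf("  %s %.5f (se %.5f)\n", lab, x$slope, x$slope_se))
  invisible(x)
}

#' Build a utility model from stated coefficients
#'
#' Constructs the same object [fit_utility_model()] returns, from an
#' intercept (utility at 0 MMD) and a per-MMD decrement, e.g. the
#' published base-case coefficients (0.85, 0.0176).
#'
#' @param intercept utility at 0 MMD, in (0, 1].
#' @param slope utility decrement per MMD (positive magnitude).
#' @param intercept_se,slope_se standard errors (0 when treated as fixed).
#' @return a `fitted_linear_model`.
#' @examples
#' m <- utility_model(0.85, 0.0176)
#' predict_utility(m, 0)   # 0.85
#' predict_utility(m, 28)  # 0.3572
#' @export
utility_model <- function(intercept, slope, intercept_se = 0, slope_se = 0) {
  stopifnot(intercept > 0, intercept <= 1, slope >= 0)
  structure(list(
    intercept = intercept, slope = slope,
    intercept_se = intercept_se, slope_se = slope_se,
    residual_sd = NA_real_, n_obs = NA_integer_,
    covariance = diag(c(intercept_se^2, slope_se^2)),
    slope_is_decrement = TRUE),
    class = "fitted_linear_model")
}

#' Predict utility at a given MMD level
#'
#' `intercept - slope * mmd`, clamped to \[0, 1\].
#'
#' @param model a `fitted_linear_model` with a decrement slope, or any
#'   list with `intercept` and `slope` fields on that convention.
#' @param mmd monthly migraine days, in \[0, 28\]; vectorised.
#' @return utility value(s) in \[0, 1\].
#' @export
predict_utility <- function(model, mmd) {
  if (any(mmd < 0 | mmd > 28))
    stop("mmd must lie in [0, 28]", call. = FALSE)
  pmin(pmax(model$intercept - model$slope * mmd, 0), 1)
}

#' Expected adverse-event disutility for an arm
#'
#' Incidence-weighted sum of catalogue disutilities,
#' \eqn{\sum_e p_e \, d_e}: the expected one-off utility loss over the
#' assessment period for a patient starting the arm's treatment.
#'
#' @param arm arm specification with an `ae_incidence` named list.
#' @param utility_spec the `utility` component of a `cea_params` object
#'   (carries the `ae_disutility` catalogue).
#' @return expected utility decrement, >= 0.
#' @export
expected_ae_disutility <- function(arm, utility_spec) {
  inc <- arm$ae_incidence
  if (!length(inc)) return(0)
  unknown <- setdiff(names(inc), names(utility_spec$ae_disutility))
  if (length(unknown))
    stop("adverse event(s) not in the disutility catalogue: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  sum(vapply(names(inc), function(ae) {
    inc[[ae]] * utility_spec$ae_disutility[[ae]]$loss
  }, numeric(1)))
}

#' Daily labour cost
#'
#' Monthly wage cost divided by working days per month, scaled by the
#' employment probability `(1 - unemployment_rate)`.
#'
#' @param wage_monthly total monthly wage cost, EUR, > 0.
#' @param working_days working days per month, > 0.
#' @param unemployment_rate in \[0, 1).
#' @return EUR per working day.
#' @examples
#' daily_labour_cost(2847.10, 22, 0.127)  # 112.97
#' @export
daily_labour_cost <- function(wage_monthly, working_days, unemployment_rate) {
  if (wage_monthly <= 0) stop("wage_monthly must be > 0", call. = FALSE)
  if (working_days <= 0) stop("working_days must be > 0", call. = FALSE)
  if (unemployment_rate < 0 || unemployment_rate >= 1)
    stop("unemployment_rate must lie in [0,1)", call. = FALSE)
  wage_monthly / working_days * (1 - unemployment_rate)
}

#' Predicted work-loss days per cycle at a given MMD
#'
#' Evaluates the fitted 3-month work-loss models at `mmd`, floors the
#' predictions at zero and rescales the 90-day MIDAS/WPAI recall window
#' to the cycle length.
#'
#' @param mmd monthly migraine days.
#' @param models list with `absenteeism` and `presenteeism`
#'   `fitted_linear_model`s (signed slopes), as returned by
#'   [fit_work_loss_models()].
#' @param cycle_length_days cycle length (default 84).
#' @return list with `absent_days` and `presenteeism_days` per cycle.
#' @export
predict_work_loss <- function(mmd, models, cycle_length_days = 84) {
  scale <- cycle_length_days / 90
  list(
    absent_days = pmax(models$absenteeism$intercept +
                         models$absenteeism$slope * mmd, 0) * scale,
    presenteeism_days = pmax(models$presenteeism$intercept +
                               models$presenteeism$slope * mmd, 0) * scale)
}

#' Indirect (productivity) cost per cycle
#'
#' Absent days are valued at a full day of labour; presenteeism days at
#' `presenteeism_fraction` of a day.
#'
#' @inheritParams predict_work_loss
#' @param labour_cost EUR per working day (see [daily_labour_cost()]).
#' @param presenteeism_fraction fraction of a workday lost per
#'   presenteeism day (default 0.5).
#' @return EUR per cycle, >= 0.
#' @export
indirect_cost_per_cycle <- function(mmd, models, labour_cost,
                                    presenteeism_fraction = 0.5,
                                    cycle_length_days = 84) {
  wl <- predict_work_loss(mmd, models, cycle_length_days)
  wl$absent_days * labour_cost +
    wl$presenteeism_days * presenteeism_fraction * labour_cost
}

#' Work-loss models from stated coefficients
#'
#' Builds the `fit_work_loss_models()` return shape directly from
#' configured intercepts and slopes (days per 3 months), as stored in the
#' `costs$work_loss` component of a parameter set.
#'
#' @param work_loss list with `absenteeism` and `presenteeism`
#'   components, each carrying `intercept` and `slope`.
#' @return list of two `fitted_linear_model`s with signed slopes.
#' @export
work_loss_models_from_config <- function(work_loss) {
  as_model <- function(cf) structure(list(
    intercept = cf$intercept, slope = cf$slope,
    intercept_se = 0, slope_se = 0, residual_sd = NA_real_,
    n_obs = NA_integer_, covariance = diag(c(0, 0)),
    slope_is_decrement = FALSE), class = "fitted_linear_model")
  list(absenteeism = as_model(work_loss$absenteeism),
       presenteeism = as_model(work_loss$presenteeism))
}
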