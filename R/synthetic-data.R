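#' Specification of the synthetic trial generator
#'
#' The generator emulates the statistical structure the downstream
#' analysis assumes about patient-level trial data: monthly migraine days
#' (MMD) from a truncated normal on \[0, 28\]; observed utility linear in
#' MMD with Gaussian noise (truncated to \[-0.5, 1\]); MIDAS absent days a
#' negative-binomial count around a mean linear in MMD; presenteeism days
#' likewise; adverse-event flags Bernoulli at arm-level incidences.
#'
#' @param n_patients number of patients.
#' @param true_utility_intercept,true_utility_slope utility at 0 MMD and
#'   utility decrement per MMD.
#' @param utility_noise_sd Gaussian noise sd on observed utility.
#' @param true_absenteeism_intercept,true_absenteeism_slope mean MIDAS
#'   absent days per 3 months at 0 MMD and per additional MMD.
#' @param true_presenteeism_intercept,true_presenteeism_slope same, for
#'   presenteeism days.
#' @param absenteeism_size negative-binomial size (dispersion) parameter;
#'   `Inf` gives Poisson-like counts.
#' @param mmd_mean,mmd_sd MMD distribution before truncation at \[0,28\].
#' @param ae_incidence named list of per-adverse-event probabilities.
#' @param rng_seed integer seed; fixed seed gives identical output.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_patients = 1000,
                       true_utility_intercept = 0.85,
                       true_utility_slope = 0.0176,
                       utility_noise_sd = 0.05,
                       true_absenteeism_intercept = 0.25,
                       true_absenteeism_slope = 0.45,
                       true_presenteeism_intercept = 0.50,
                       true_presenteeism_slope = 0.55,
                       absenteeism_size = 8,
                       mmd_mean = 9.44, mmd_sd = 5,
                       ae_incidence = list(),
                       rng_seed = 1L) {
  spec <- list(n_patients = n_patients,
               true_utility_intercept = true_utility_intercept,
               true_utility_slope = true_utility_slope,
               utility_noise_sd = utility_noise_sd,
               true_absenteeism_intercept = true_absenteeism_intercept,
               true_absenteeism_slope = true_absenteeism_slope,
               true_presenteeism_intercept = true_presenteeism_intercept,
               true_presenteeism_slope = true_presenteeism_slope,
               absenteeism_size = absenteeism_size,
               mmd_mean = mmd_mean, mmd_sd = mmd_sd,
               ae_incidence = ae_incidence,
               rng_seed = as.integer(rng_seed))
  validate_synth_spec(spec)
  class(spec) <- "synth_spec"
  spec
}

validate_synth_spec <- function(spec) {
  if (!is.numeric(spec$n_patients) || spec$n_patients < 1)
    stop("n_patients must be >= 1", call. = FALSE)
  for (f in c("utility_noise_sd", "mmd_sd"))
    if (spec[[f]] < 0) stop(f, " must be >= 0", call. = FALSE)
  if (spec$absenteeism_size <= 0)
    stop("absenteeism_size must be > 0", call. = FALSE)
  for (ae in names(spec$ae_incidence)) {
    p <- spec$ae_incidence[[ae]]
    if (p < 0 || p > 1) stop("ae_incidence$", ae, " must lie in [0,1]",
                             call. = FALSE)
  }
  invisible(spec)
}

rtruncnorm01 <- function(n, mean, sd, lower, upper) {
  mean <- rep_len(mean, n)
  if (sd == 0) return(pmin(pmax(mean, lower), upper))
  x <- stats::rnorm(n, mean, sd)
  # resample out-of-range draws; truncation bounds are wide so this ends
  repeat {
    bad <- which(x < lower | x > upper)
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd)
  }
  x
}

#' Generate a synthetic patient-level trial dataset
#'
#' @param spec a [synth_spec()].
#' @param arm arm label to attach.
#' @return data frame with one row per patient: `patient_id`, `arm`,
#'   `mmd`, `utility_observed`, `midas_days_absent`, `presenteeism_days`,
#'   `wpai_presenteeism_pct`, plus one `ae_<name>` logical column per
#'   adverse event in the spec.
#' @examples
#' d <- generate_trial(synth_spec(n_patients = 50, rng_seed = 7))
#' range(d$mmd)  # within [0, 28]
#' @export
generate_trial <- function(spec, arm = "arm_a") {
  validate_synth_spec(spec)
  set.seed(spec$rng_seed)
  n <- spec$n_patients
  mmd <- rtruncnorm01(n, rep(spec$mmd_mean, n), spec$mmd_sd, 0, 28)
  u_mean <- spec$true_utility_intercept - spec$true_utility_slope * mmd
  utility <- if (spec$utility_noise_sd == 0) u_mean else
    pmin(pmax(stats::rnorm(n, u_mean, spec$utility_noise_sd), -0.5), 1)
  work <- draw_work_loss(spec, mmd)
  out <- data.frame(
    patient_id = seq_len(n),
    arm = arm,
    mmd = mmd,
    utility_observed = utility,
    midas_days_absent = work$absent,
    presenteeism_days = work$present,
    wpai_presenteeism_pct = work$wpai_pct,
    stringsAsFactors = FALSE)
  for (ae in names(spec$ae_incidence))
    out[[paste0("ae_", ae)]] <-
      stats::runif(n) < spec$ae_incidence[[ae]]
  out
}

draw_work_loss <- function(spec, mmd) {
  n <- length(mmd)
  mu_abs <- pmax(spec$true_absenteeism_intercept +
                   spec$true_absenteeism_slope * mmd, 1e-9)
  mu_pre <- pmax(spec$true_presenteeism_intercept +
                   spec$true_presenteeism_slope * mmd, 1e-9)
  absent <- pmin(stats::rnbinom(n, size = spec$absenteeism_size, mu = mu_abs),
                 90)
  present <- pmin(stats::rnbinom(n, size = spec$absenteeism_size, mu = mu_pre),
                  90)
  # WPAI expresses presenteeism as % of worked time impaired (3 months ~
  # 66 working days)
  wpai_pct <- pmin(100 * present / 66, 100)
  list(absent = absent, present = present, wpai_pct = wpai_pct)
}

#' Generate work-loss (MIDAS / WPAI) records only
#'
#' Same generative model as [generate_trial()] but restricted to the
#' columns the work-loss regressions consume.
#'
#' @inheritParams generate_trial
#' @return data frame with `patient_id`, `mmd`, `midas_days_absent`,
#'   `presenteeism_days`, `wpai_presenteeism_pct`.
#' @export
generate_midas_wpai <- function(spec) {
  d <- generate_trial(spec)
  d[c("patient_id", "mmd", "midas_days_absent", "presenteeism_days",
      "wpai_presenteeism_pct")]
}

#' Generate a synthetic life table
#'
#' A Gompertz-like synthetic life table: annual mortality at the anchor
#' age grows geometrically with age, with a female/male level contrast.
#' It stands in for a national life table in examples and packaged
#' defaults; any real table with columns `age,sex,qx` can replace it.
#'
#' @param base_annual_mortality_at_anchor annual mortality probability at
#'   `anchor_age` (sex-averaged), in (0,1).
#' @param annual_growth_factor geometric growth per year of age, >= 1.
#' @param anchor_age,max_age age range covered.
#' @param female_factor,male_factor multiplicative sex contrasts.
#' @return data frame with columns `age`, `sex`, `qx`; `qx` capped at 1
#'   (with a warning) if growth pushes it past 1 before `max_age`.
#' @examples
#' lt <- generate_life_table(0.001, 1.09, max_age = 101)
#' subset(lt, age == 51 & sex == "F")$qx  # 0.001 * 1.09^10 * 0.8
#' @export
generate_life_table <- function(base_annual_mortality_at_anchor = 0.001,
                                annual_growth_factor = 1.09,
                                anchor_age = 41, max_age = 101,
                                female_factor = 0.8, male_factor = 1.2) {
  if (base_annual_mortality_at_anchor <= 0 ||
      base_annual_mortality_at_anchor >= 1)
    stop("base annual mortality must lie in (0,1)", call. = FALSE)
  if (annual_growth_factor < 1)
    stop("annual growth factor must be >= 1", call. = FALSE)
  ages <- anchor_age:max_age
  qx_base <- base_annual_mortality_at_anchor *
    annual_growth_factor^(ages - anchor_age)
  qx <- c(qx_base * female_factor, qx_base * male_factor)
  if (any(qx > 1)) {
    warning("qx exceeded 1 before max_age; capped at 1")
    qx <- pmin(qx, 1)
  }
  data.frame(age = rep(ages, 2),
             sex = rep(c("F", "M"), each = length(ages)),
             qx = qx)
}
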