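#' Moment-match a parametric distribution to a mean and standard error
#'
#' Families follow standard health-economic conventions: beta for
#' probabilities and utility losses, gamma for rates and resource use,
#' lognormal for odds ratios, multivariate normal for regression
#' coefficients.  A zero standard error degenerates to a point mass.
#'
#' Parameterisations: beta `alpha = m*nu`, `beta = (1-m)*nu` with
#' `nu = m(1-m)/se^2 - 1`; gamma `shape = (m/se)^2`, `rate = m/se^2`;
#' lognormal `sigma^2 = log(1 + se^2/m^2)`, `mu = log(m) - sigma^2/2`.
#'
#' @param family `"beta"`, `"gamma"`, `"lognormal"` or `"fixed"`.
#' @param mean,se target mean and standard error.
#' @return a `psa_dist`: list with `family`, matched parameters, and a
#'   `draw(n)` function.
#' @examples
#' d <- moment_match("beta", 0.5, 0.1)  # alpha = beta = 12
#' d$alpha
#' @export
moment_match <- function(family = c("beta", "gamma", "lognormal", "fixed"),
                         mean, se) {
  family <- match.arg(family)
  if (se < 0) stop("se must be >= 0", call. = FALSE)
  if (se == 0 || family == "fixed") {
    return(structure(list(family = "fixed", mean = mean, se = 0,
                          draw = function(n) rep(mean, n)),
                     class = "psa_dist"))
  }
  out <- switch(family,
    beta = {
      if (mean <= 0 || mean >= 1)
        stop("beta mean must lie in (0,1)", call. = FALSE)
      if (se^2 >= mean * (1 - mean))
        stop("beta: se^2 must be < mean*(1-mean)", call. = FALSE)
      nu <- mean * (1 - mean) / se^2 - 1
      a <- mean * nu; b <- (1 - mean) * nu
      list(alpha = a, beta = b,
           draw = function(n) stats::rbeta(n, a, b))
    },
    gamma = {
      if (mean <= 0) stop("gamma mean must be > 0", call. = FALSE)
      shape <- (mean / se)^2; rate <- mean / se^2
      list(shape = shape, rate = rate,
           draw = function(n) stats::rgamma(n, shape, rate))
    },
    lognormal = {
      if (mean <= 0) stop("lognormal mean must be > 0", call. = FALSE)
      s2 <- log(1 + se^2 / mean^2)
      mu <- log(mean) - s2 / 2
      list(meanlog = mu, sdlog = sqrt(s2),
           draw = function(n) stats::rlnorm(n, mu, sqrt(s2)))
    })
  structure(c(list(family = family, mean = mean, se = se), out),
            class = "psa_dist")
}

#' Default PSA distribution specifications for a parameter set
#'
#' Builds the named list of sampling specs [sample_parameter_set()]
#' consumes: lognormal for the response odds ratio, beta for the
#' comparator response probability and adverse-event disutilities,
#' gamma for discontinuation probabilities and resource unit costs, and
#' (multivariate) normal for the utility regression coefficients.
#' Standard errors printed with the base case are used where available;
#' where none exists the spec's `se` defaults to 20% of the mean
#' (an analyst convention, adjustable per entry), and the comparator
#' response probability gets a binomial standard error at an effective
#' trial size of 500.  Parameters with `se = 0` stay fixed.
#'
#' @param params a `cea_params` object.
#' @return named list of spec entries (`path`, `family`, `mean`, `se`),
#'   plus one `utility_mvn` entry carrying the coefficient mean vector
#'   and covariance.
#' @export
default_psa_specs <- function(params) {
  specs <- list()
  cmp <- params$arms$comparator
  n_eff <- 500
  specs$response_prob_comparator <- list(
    path = "arms/comparator/response_prob", family = "beta",
    mean = cmp$response_prob,
    se = sqrt(cmp$response_prob * (1 - cmp$response_prob) / n_eff))
  if (!is.null(cmp$response_or))
    specs$response_or <- list(
      path = "arms/comparator/response_or", family = "lognormal",
      mean = cmp$response_or, se = cmp$response_or_se %||% 0)
  for (an in c("intervention", "comparator")) {
    a <- params$arms[[an]]
    specs[[paste0("longterm_disc_", an)]] <- list(
      path = paste0("arms/", an, "/longterm_discontinuation_prob_per_cycle"),
      family = "gamma",
      mean = a$longterm_discontinuation_prob_per_cycle,
      se = a$longterm_discontinuation_se %||%
        (0.2 * a$longterm_discontinuation_prob_per_cycle))
    specs[[paste0("ae_disc_", an)]] <- list(
      path = paste0("arms/", an, "/ae_discontinuation_prob_cycle1"),
      family = "beta",
      mean = a$ae_discontinuation_prob_cycle1,
      se = 0.2 * a$ae_discontinuation_prob_cycle1)
  }
  for (rn in names(params$costs$resources)) {
    uc <- params$costs$resources[[rn]]$unit_cost
    specs[[paste0("unit_cost_", rn)]] <- list(
      path = paste0("costs/resources/", rn, "/unit_cost"),
      family = "gamma", mean = uc, se = 0.2 * uc)
  }
  for (ae in names(params$utility$ae_disutility)) {
    d <- params$utility$ae_disutility[[ae]]
    specs[[paste0("ae_disutility_", ae)]] <- list(
      path = paste0("utility/ae_disutility/", ae, "/loss"),
      family = "beta", mean = d$loss, se = d$se)
  }
  specs$utility_mvn <- list(
    family = "multivariate_normal",
    paths = c("utility/intercept_u0", "utility/slope_per_mmd"),
    mean = c(params$utility$intercept_u0, params$utility$slope_per_mmd),
    covariance = diag(c(params$utility$intercept_se^2,
                        params$utility$slope_se^2)))
  specs
}

# beta disutility specs whose se^2 >= m(1-m) cannot be matched; they are
# clamped to the largest feasible se with a one-time message upstream
feasible_beta_se <- function(mean, se) {
  cap <- sqrt(mean * (1 - mean)) * 0.999
  min(se, cap)
}

#' Apply an odds ratio to a baseline response probability
#'
#' `p_int = OR * odds(p) / (1 + OR * odds(p))` with `odds(p) = p/(1-p)`.
#'
#' @param p baseline probability in (0, 1).
#' @param odds_ratio positive odds ratio.
#' @return transformed probability.
#' @examples
#' response_from_odds_ratio(0.18, 2.76)  # 0.3773
#' @export
response_from_odds_ratio <- function(p, odds_ratio) {
  stopifnot(p > 0, p < 1, odds_ratio > 0)
  odds <- odds_ratio * p / (1 - p)
  odds / (1 + odds)
}

#' Draw one parameter set for the PSA
#'
#' Samples every uncertain parameter from its spec, clamps sampled
#' probabilities to \[0, 1\], and re-derives the intervention response
#' probability from the sampled comparator probability and odds ratio on
#' the odds scale:
#' `p_int = OR * odds(p_cmp) / (1 + OR * odds(p_cmp))`.
#'
#' @param base the base `cea_params` object.
#' @param specs spec list from [default_psa_specs()] (or a subset).
#' @return a sampled `cea_params` object.
#' @export
sample_parameter_set <- function(base, specs) {
  p <- base
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    if (identical(sp$family, "multivariate_normal")) {
      z <- as.numeric(MASS::mvrnorm(1, sp$mean, sp$covariance))
      for (j in seq_along(sp$paths))
        p <- set_param(p, sp$paths[j], z[j])
      next
    }
    se <- sp$se
    if (identical(sp$family, "beta")) se <- feasible_beta_se(sp$mean, se)
    val <- moment_match(sp$family, sp$mean, se)$draw(1)
    if (sp$family == "beta" ||
        grepl("prob", sp$path %||% "", fixed = TRUE))
      val <- min(max(val, 0), 1)
    p <- set_param(p, sp$path, val)
  }
  # keep the utility line admissible over the 0-28 MMD spectrum
  p$utility$intercept_u0 <- min(max(p$utility$intercept_u0, 1e-6), 1)
  p$utility$slope_per_mmd <- min(max(p$utility$slope_per_mmd, 0),
                                 p$utility$intercept_u0 / 28)
  # intervention response is derived on the odds scale from the sampled
  # comparator response and odds ratio; when neither moved (degenerate
  # specs) the base-case intervention probability is kept as printed
  or_moved <- !is.null(p$arms$comparator$response_or) &&
    (p$arms$comparator$response_or != base$arms$comparator$response_or ||
     p$arms$comparator$response_prob != base$arms$comparator$response_prob)
  if (or_moved) {
    pc <- p$arms$comparator$response_prob
    odds <- p$arms$comparator$response_or * pc / (1 - pc)
    p$arms$intervention$response_prob <- odds / (1 + odds)
  }
  p
}

#' Run the probabilistic sensitivity analysis
#'
#' One full model evaluation per Monte Carlo draw.  Reproducibility: a
#' root seed spawns one child seed per iteration, so iteration `i` is
#' identical whatever the total number of iterations.
#'
#' @param base the base `cea_params` object.
#' @param specs distribution specs (default [default_psa_specs()]).
#' @param n_iterations number of draws (default from
#'   `base$settings$psa_iterations`).
#' @param seed root seed (default from `base$settings$rng_seed`).
#' @param wtp_grid willingness-to-pay grid for the CEAC, EUR/QALY.
#' @return a `psa_result`: list with `iterations` (data frame of
#'   `delta_cost`, `delta_qaly`, `delta_md`), `ceac` (data frame `wtp`,
#'   `prob_cost_effective`), `crossing` (lowest grid WTP where the curve
#'   exceeds 0.5, `NA` if never), `seed`, `n_iterations`.
#' @export
run_psa <- function(base, specs = default_psa_specs(base),
                    n_iterations = NULL, seed = NULL,
                    wtp_grid = seq(0, 50000, by = 100)) {
  assert_valid_parameters(base)
  n_iterations <- n_iterations %||% base$settings$psa_iterations
  seed <- seed %||% base$settings$rng_seed
  # the MMD trajectory is a structural input: calibrated once on the base
  # case and held fixed while probabilities, costs and utilities vary
  mmd_fix <- calibrated_mmd_assignments(base)
  dc <- dq <- dmd <- numeric(n_iterations)
  for (i in seq_len(n_iterations)) {
    set.seed((seed %% 1000003L) * 2048L + i)
    p <- sample_parameter_set(base, specs)
    r <- tryCatch(run_cea(p, validate = FALSE, mmd_assignments = mmd_fix),
                  error = function(e)
                    stop(sprintf("PSA iteration %d failed: %s", i,
                                 conditionMessage(e)), call. = FALSE))
    dc[i] <- r$ce$delta_cost; dq[i] <- r$ce$delta_qaly
    dmd[i] <- r$ce$delta_md
  }
  iters <- data.frame(iteration = seq_len(n_iterations),
                      delta_cost = dc, delta_qaly = dq, delta_md = dmd)
  curve <- ceac(iters, wtp_grid)
  cross <- curve$wtp[curve$prob_cost_effective > 0.5][1]
  structure(list(iterations = iters, ceac = curve,
                 crossing = if (length(cross)) cross else NA_real_,
                 seed = seed, n_iterations = n_iterations),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay `lambda`, the fraction of PSA iterations
#' with positive net monetary benefit `lambda * dQALY - dCost > 0`.
#'
#' @param iterations data frame with `delta_cost` and `delta_qaly` (a
#'   `psa_result` is also accepted).
#' @param wtp_grid numeric grid of at least 2 WTP points.
#' @return data frame `wtp`, `prob_cost_effective`.
#' @export
ceac <- function(iterations, wtp_grid = seq(0, 50000, by = 100)) {
  if (inherits(iterations, "psa_result")) iterations <- iterations$iterations
  if (!nrow(iterations)) stop("no PSA iterations", call. = FALSE)
  if (length(wtp_grid) < 2) stop("wtp_grid needs >= 2 points", call. = FALSE)
  prob <- vapply(wtp_grid, function(l)
    mean(l * iterations$delta_qaly - iterations$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}

#' One-way deterministic (tornado) sensitivity analysis
#'
#' Each listed parameter is set to 0.8x and 1.2x its base value
#' (probabilities capped at 1, with a warning) and the model is rerun;
#' entries are returned sorted by descending outcome range.  The default
#' outcome is the net monetary benefit at the configured threshold (the
#' ICER is unstable under sign changes); `outcome = "icer"` is also
#' available.
#'
#' @param base the base `cea_params` object.
#' @param parameter_paths character vector of parameter paths (see
#'   [get_param()]); default [default_tornado_parameters()].
#' @param rel_change relative perturbation (default 0.20).
#' @param outcome `"nmb"` or `"icer"`.
#' @return data frame, one row per parameter: `parameter`, `base_value`,
#'   `low_value`, `high_value`, `outcome_low`, `outcome_high`,
#'   `range_width`, plus the base outcome as attribute `base_outcome`.
#' @export
tornado <- function(base, parameter_paths = default_tornado_parameters(base),
                    rel_change = 0.20, outcome = c("nmb", "icer")) {
  outcome <- match.arg(outcome)
  assert_valid_parameters(base)
  out_of <- function(run) if (outcome == "nmb") run$ce$nmb else
    run$ce$icer_per_qaly
  mmd_fix <- calibrated_mmd_assignments(base)
  base_run <- run_cea(base, validate = FALSE, mmd_assignments = mmd_fix)
  is_prob <- function(path) grepl("prob|fraction|rate", path)
  rows <- lapply(parameter_paths, function(path) {
    b <- get_param(base, path)
    lo <- b * (1 - rel_change)
    hi <- b * (1 + rel_change)
    if (is_prob(path) && hi > 1) {
      warning("perturbed probability at ", path, " capped at 1")
      hi <- 1
    }
    r_lo <- run_cea(set_param(base, path, lo), validate = FALSE,
                    mmd_assignments = mmd_fix)
    r_hi <- run_cea(set_param(base, path, hi), validate = FALSE,
                    mmd_assignments = mmd_fix)
    data.frame(parameter = path, base_value = b,
               low_value = lo, high_value = hi,
               outcome_low = out_of(r_lo), outcome_high = out_of(r_hi))
  })
  res <- do.call(rbind, rows)
  res$range_width <- abs(res$outcome_high - res$outcome_low)
  res <- res[order(-res$range_width), ]
  rownames(res) <- NULL
  attr(res, "base_outcome") <- out_of(base_run)
  attr(res, "outcome") <- outcome
  res
}

#' Default tornado parameter registry
#'
#' The model inputs a practitioner would routinely vary: response
#' probabilities, discontinuation probabilities, the utility decrement
#' per MMD, drug prices, resource unit costs and the labour-cost inputs
#' (the latter only under the societal perspective).
#'
#' @param params a `cea_params` object.
#' @return character vector of parameter paths.
#' @export
default_tornado_parameters <- function(params) {
  paths <- c(
    "arms/intervention/response_prob",
    "arms/comparator/response_prob",
    "arms/intervention/longterm_discontinuation_prob_per_cycle",
    "arms/comparator/longterm_discontinuation_prob_per_cycle",
    "arms/intervention/ae_discontinuation_prob_cycle1",
    "arms/comparator/ae_discontinuation_prob_cycle1",
    "utility/slope_per_mmd",
    "arms/intervention/drug_price_per_dose",
    "arms/comparator/drug_price_per_dose",
    paste0("costs/resources/", names(params$costs$resources), "/unit_cost"))
  if (identical(params$settings$perspective, "societal"))
    paths <- c(paths, "costs/wage_monthly", "costs/unemployment_rate")
  paths
}

#' Run a named scenario
#'
#' A scenario is a parameter overlay applied before a full rerun.
#' Registered scenarios: `"healthcare_base"` (identity),
#' `"societal"` (perspective switch; adds the indirect-cost category),
#' `"wpai_productivity"` (societal perspective with the WPAI-calibrated
#' work-loss coefficients), `"no_discounting"` (both rates 0).
#'
#' @param base the base `cea_params` object.
#' @param scenario_name one of the registered names.
#' @return a `cea_run` (see [run_cea()]) with the scenario name attached
#'   as attribute `scenario`.
#' @export
run_scenario <- function(base, scenario_name) {
  overlays <- list(
    healthcare_base = identity,
    societal = function(p) { p$settings$perspective <- "societal"; p },
    wpai_productivity = function(p) {
      p$settings$perspective <- "societal"
      p$costs$work_loss$absenteeism <- p$costs$work_loss$wpai$absenteeism
      p$costs$work_loss$presenteeism <- p$costs$work_loss$wpai$presenteeism
      p
    },
    no_discounting = function(p) {
      p$settings$discount_rate_costs <- 0
      p$settings$discount_rate_effects <- 0
      p
    })
  if (!scenario_name %in% names(overlays))
    stop("unknown scenario: ", scenario_name, "; registered: ",
         paste(names(overlays), collapse = ", "), call. = FALSE)
  run <- run_cea(overlays[[scenario_name]](base))
  attr(run, "scenario") <- scenario_name
  run
}
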