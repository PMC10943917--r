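DAYS_PER_MONTH <- 30.4375   # calendar mean; converts monthly MMD to MD counts
DAYS_PER_YEAR <- 365.25

#' MMD band labels
#' @export
mmd_band_labels <- c("no_migraine", "low", "intermediate", "high", "chronic")

#' Classify an MMD level into its frequency band
#'
#' Bands partition the 0–28 MMD spectrum: 0 (no migraine), 1–3 (low), 4–7
#' (intermediate), 8–14 (high), 15+ (chronic).  Fractional MMD is
#' assigned by its floor.
#'
#' @param mmd monthly migraine days in \[0, 28\]; vectorised.
#' @return integer band index 1..5 with the label as a names attribute.
#' @examples
#' classify_band(7.42)  # intermediate
#' @export
classify_band <- function(mmd) {
  if (any(mmd < 0 | mmd > 28))
    stop("mmd must lie in [0, 28]", call. = FALSE)
  f <- floor(mmd)
  idx <- ifelse(f == 0, 1L,
         ifelse(f <= 3, 2L,
         ifelse(f <= 7, 3L,
         ifelse(f <= 14, 4L, 5L))))
  names(idx) <- mmd_band_labels[idx]
  idx
}

#' Discount factor at a cycle index
#'
#' `(1 + r)^(-k * cycle_days / 365.25)`: continuous-in-years compounding
#' evaluated at the end of cycle `k`.
#'
#' @param cycle_index k >= 0; vectorised.
#' @param rate annual discount rate in \[0, 1).
#' @param cycle_days cycle length in days.
#' @return factor in (0, 1\].
#' @export
discount_factor <- function(cycle_index, rate, cycle_days = 84) {
  (1 + rate)^(-cycle_index * cycle_days / DAYS_PER_YEAR)
}

#' Direct cost of one cycle in a given MMD state
#'
#' Band resource use (unit cost x units x fraction of patients), plus
#' acute-medication cost at the midpoint of the band's published range,
#' plus the preventive drug cost when on treatment.  The pharmacy-visit
#' resource accrues only in arms on a hospital-dispensed drug.
#'
#' @param mmd the MMD attached to the state.
#' @param costs the `costs` component of a `cea_params` object.
#' @param arm arm specification (hospital dispensing flag, drug price).
#' @param on_treatment does the state accrue preventive drug cost?
#' @return list with components `resource`, `acute`, `drug`, `total`
#'   (EUR per cycle).
#' @export
cycle_direct_cost <- function(mmd, costs, arm, on_treatment = FALSE) {
  b <- classify_band(mmd)
  resource <- 0
  for (r in costs$resources) {
    if (isTRUE(r$hospital_dispensed_only) && !isTRUE(arm$hospital_dispensed))
      next
    resource <- resource + r$unit_cost * r$units[b] * r$fraction[b]
  }
  resource <- resource * costs$inflation_multiplier
  acute <- sum(vapply(costs$acute_medication, function(m)
    (m$low[b] + m$high[b]) / 2, numeric(1))) * costs$inflation_multiplier
  drug <- if (on_treatment) drug_cost_per_cycle(arm, costs) else 0
  list(resource = resource, acute = acute, drug = drug,
       total = resource + acute + drug)
}

#' QALYs accrued over one cycle in a given MMD state
#'
#' Utility at the state's MMD times the year-fraction of the cycle,
#' minus any pro-rated adverse-event decrement.
#'
#' @param mmd the MMD attached to the state.
#' @param utility_model a decrement-slope utility model (see
#'   [utility_model()]).
#' @param ae_decrement one-off utility decrement applied over this cycle
#'   (0 except in the assessment cycle).
#' @param cycle_days cycle length in days.
#' @return QALYs per person-cycle (floored at 0).
#' @export
cycle_qaly <- function(mmd, utility_model, ae_decrement = 0,
                       cycle_days = 84) {
  yf <- cycle_days / DAYS_PER_YEAR
  pmax((predict_utility(utility_model, mmd) - ae_decrement) * yf, 0)
}

#' Accrue a cohort trace into per-arm totals
#'
#' Sums occupancy-weighted, discounted costs (by category), QALYs and
#' migraine days over the trace.  Conventions: costs and QALYs are
#' discounted at their respective rates; migraine days are an
#' undiscounted count (`mmd x cycle_days / 30.4375` per person-cycle);
#' everyone is on drug during the assessment cycle (cycle 1), thereafter
#' only the on-treatment state; the expected adverse-event disutility is
#' a one-off decrement in cycle 1; the dead state accrues nothing;
#' indirect (productivity) costs accrue only under the societal
#' perspective.
#'
#' @param trace a `cohort_trace` from [run_markov_trace()].
#' @param params the full `cea_params` object.
#' @param arm the arm specification the trace was run under.
#' @param work_loss_models optional list of fitted work-loss models;
#'   defaults to the configured coefficients
#'   (`work_loss_models_from_config(params$costs$work_loss)`).
#' @return an `arm_result`: list with `label`, `totals` (named numeric:
#'   discounted/undiscounted cost, cost categories, QALYs, migraine
#'   days) and the per-cycle accrual table `cycles`.
#' @export
accrue <- function(trace, params, arm, work_loss_models = NULL) {
  s <- params$settings
  cd <- s$cycle_length_days
  umod <- utility_model(params$utility$intercept_u0,
                        params$utility$slope_per_mmd)
  ae_dec <- expected_ae_disutility(arm, params$utility)
  societal <- identical(s$perspective, "societal")
  if (societal && is.null(work_loss_models))
    work_loss_models <- work_loss_models_from_config(params$costs$work_loss)
  labour <- if (societal)
    daily_labour_cost(params$costs$wage_monthly,
                      params$costs$working_days_per_month,
                      params$costs$unemployment_rate) else 0

  rows <- trace[trace$cycle >= 1, ]
  K <- nrow(rows)
  per_cycle <- data.frame(cycle = rows$cycle, weight = rows$weight,
                          cost_drug = 0, cost_acute = 0, cost_resource = 0,
                          cost_indirect = 0, qaly = 0, md = 0,
                          df_cost = discount_factor(rows$cycle,
                                                    s$discount_rate_costs, cd),
                          df_eff = discount_factor(rows$cycle,
                                                   s$discount_rate_effects, cd))
  for (i in seq_len(K)) {
    w <- rows$weight[i]
    states <- list(
      list(occ = rows$on_treatment[i], mmd = rows$mmd_on[i],
           on_drug = TRUE),
      list(occ = rows$discontinued[i], mmd = rows$mmd_disc[i],
           on_drug = FALSE))
    # during the assessment cycle the whole living cohort is on drug
    if (rows$cycle[i] == 1) {
      per_cycle$cost_drug[i] <- (rows$on_treatment[i] + rows$discontinued[i]) *
        drug_cost_per_cycle(arm, params$costs) * w
    }
    for (st in states) {
      if (st$occ <= 0) next
      cc <- cycle_direct_cost(st$mmd, params$costs, arm, on_treatment = FALSE)
      per_cycle$cost_resource[i] <- per_cycle$cost_resource[i] +
        st$occ * cc$resource * w
      per_cycle$cost_acute[i] <- per_cycle$cost_acute[i] +
        st$occ * cc$acute * w
      if (rows$cycle[i] > 1 && st$on_drug)
        per_cycle$cost_drug[i] <- per_cycle$cost_drug[i] +
          st$occ * drug_cost_per_cycle(arm, params$costs) * w
      dec <- if (rows$cycle[i] == 1) ae_dec else 0
      per_cycle$qaly[i] <- per_cycle$qaly[i] +
        st$occ * cycle_qaly(st$mmd, umod, dec, cd) * w
      per_cycle$md[i] <- per_cycle$md[i] +
        st$occ * st$mmd * (cd / DAYS_PER_MONTH) * w
      if (societal)
        per_cycle$cost_indirect[i] <- per_cycle$cost_indirect[i] +
          st$occ * indirect_cost_per_cycle(st$mmd, work_loss_models, labour,
                                           params$costs$presenteeism_day_fraction,
                                           cd) * w
    }
  }
  per_cycle$cost_total <- per_cycle$cost_drug + per_cycle$cost_acute +
    per_cycle$cost_resource + per_cycle$cost_indirect

  tot <- function(col, df) sum(per_cycle[[col]] * df)
  totals <- c(
    cost_discounted        = tot("cost_total", per_cycle$df_cost),
    cost_undiscounted      = tot("cost_total", 1),
    cost_drug_discounted   = tot("cost_drug", per_cycle$df_cost),
    cost_acute_discounted  = tot("cost_acute", per_cycle$df_cost),
    cost_resource_discounted = tot("cost_resource", per_cycle$df_cost),
    cost_indirect_discounted = tot("cost_indirect", per_cycle$df_cost),
    qalys_discounted       = tot("qaly", per_cycle$df_eff),
    qalys_undiscounted     = tot("qaly", 1),
    migraine_days          = tot("md", 1))
  structure(list(label = arm$name, totals = totals, cycles = per_cycle),
            class = "arm_result")
}

#' Construct an arm result from stated totals
#'
#' Builds the minimal `arm_result` object [compare_arms()] consumes from
#' externally given totals (e.g. published per-arm costs, QALYs and
#' migraine days), for incremental arithmetic without rerunning the
#' model.
#'
#' @param total_cost discounted total cost, EUR.
#' @param total_qalys discounted QALYs.
#' @param total_md cumulative migraine days.
#' @param label arm name.
#' @return an `arm_result`.
#' @examples
#' topi <- arm_result(17059, 5.8839, 1049, "topiramate")
#' eren <- arm_result(21479, 6.1150, 877, "erenumab")
#' compare_arms(eren, topi)
#' @export
arm_result <- function(total_cost, total_qalys, total_md, label = "arm") {
  structure(list(
    label = label,
    totals = c(cost_discounted = total_cost,
               cost_undiscounted = NA_real_,
               cost_drug_discounted = NA_real_,
               cost_acute_discounted = NA_real_,
               cost_resource_discounted = NA_real_,
               cost_indirect_discounted = NA_real_,
               qalys_discounted = total_qalys,
               qalys_undiscounted = NA_real_,
               migraine_days = total_md),
    cycles = NULL), class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  t <- x$totals
  cat(sprintf("<arm_result> %s\n", x$label))
  cat(sprintf("  cost (disc.)  EUR %10.2f\n", t["cost_discounted"]))
  cat(sprintf("  QALYs (disc.) %10.4f\n", t["qalys_discounted"]))
  cat(sprintf("  migraine days %10.1f\n", t["migraine_days"]))
  invisible(x)
}

#' Incremental cost-effectiveness comparison of two arms
#'
#' Deltas are intervention minus comparator; migraine days avoided is
#' comparator minus intervention.  The ICER is flagged undefined under
#' dominance (either direction) or a zero QALY difference.
#'
#' @param intervention,comparator `arm_result` objects.
#' @param wtp_threshold willingness-to-pay per QALY used for the net
#'   monetary benefit.
#' @return a `ce_result`: list with `delta_cost`, `delta_qaly`,
#'   `delta_md` (days avoided), `icer_per_qaly`, `cost_per_md_avoided`,
#'   `nmb`, `dominance` and the two labels.
#' @export
compare_arms <- function(intervention, comparator, wtp_threshold = 30000) {
  ti <- intervention$totals; tc <- comparator$totals
  dc <- unname(ti["cost_discounted"] - tc["cost_discounted"])
  dq <- unname(ti["qalys_discounted"] - tc["qalys_discounted"])
  dmd <- unname(tc["migraine_days"] - ti["migraine_days"])
  dominance <- if (dc < 0 && dq > 0) "intervention_dominant"
    else if (dc > 0 && dq < 0) "intervention_dominated"
    else "none"
  icer <- if (dominance != "none" || dq == 0) NA_real_ else dc / dq
  cpmd <- if (dmd == 0) NA_real_ else dc / dmd
  structure(list(
    intervention = intervention$label, comparator = comparator$label,
    delta_cost = dc, delta_qaly = dq, delta_md = dmd,
    icer_per_qaly = icer, cost_per_md_avoided = cpmd,
    nmb = wtp_threshold * dq - dc,
    wtp_threshold = wtp_threshold,
    dominance = dominance), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("<ce_result> %s vs %s\n", x$intervention, x$comparator))
  cat(sprintf("  incremental cost  EUR %10.2f\n", x$delta_cost))
  cat(sprintf("  incremental QALYs %10.4f\n", x$delta_qaly))
  cat(sprintf("  MDs avoided       %10.1f\n", x$delta_md))
  if (x$dominance == "none") {
    cat(sprintf("  ICER              EUR %10.0f /QALY\n", x$icer_per_qaly))
    cat(sprintf("  cost per MD avoided EUR %8.2f\n", x$cost_per_md_avoided))
  } else {
    cat(sprintf("  dominance: %s (ICER undefined)\n", x$dominance))
  }
  cat(sprintf("  NMB at EUR %d/QALY: %.0f\n", x$wtp_threshold, x$nmb))
  invisible(x)
}
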