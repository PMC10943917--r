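em <- default_parameters("EM")

test_that("MMD bands are exhaustive, exclusive, and floor-assigned", {
  expect_equal(names(classify_band(0)), "no_migraine")
  expect_equal(names(classify_band(7.42)), "intermediate")
  expect_equal(names(classify_band(15)), "chronic")
  expect_equal(names(classify_band(28)), "chronic")
  mmd <- seq(0, 28, by = 0.5)
  idx <- classify_band(mmd)
  expect_true(all(idx %in% 1:5))
  expect_true(all(diff(idx) >= 0))  # monotone in MMD
  # floor rule at band edges
  expect_equal(unname(classify_band(3.9)), 2L)
  expect_equal(unname(classify_band(4.0)), 3L)
  expect_error(classify_band(29), "\\[0, 28\\]")
})

test_that("discount factor follows (1+r)^(-k * cycle/365.25)", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(4, 0.03), 1.03^(-4 * 84 / 365.25))
  expect_equal(discount_factor(4, 0.03), 0.97317, tolerance = 1e-5)
  expect_equal(discount_factor(0:10, 0), rep(1, 11))
})

test_that("direct cycle cost assembles resources, acute medication and drug", {
  costs <- em$costs
  topi <- em$arms$comparator   # not hospital-dispensed
  eren <- em$arms$intervention
  # no-migraine band off treatment: only the fixed other-medication cost
  c0 <- cycle_direct_cost(0, costs, topi, on_treatment = FALSE)
  expect_equal(c0$resource, 0)
  expect_equal(c0$acute, 3.56)
  expect_equal(c0$total, 3.56)
  # chronic band: hospitalisation contributes 17% x unit cost
  c5 <- cycle_direct_cost(20, costs, topi, on_treatment = FALSE)
  expect_equal(round(0.17 * 2044.61, 2), 347.58)
  hosp_share <- 0.17 * 2044.61
  expect_gt(c5$resource, hosp_share)
  # chronic triptan midpoint
  expect_equal((21.70 + 41.10) / 2, 31.40)
  expect_equal(c5$acute, 31.40 + (13.50 + 22.20) / 2)
  # pharmacy visit only for hospital-dispensed arms
  c5e <- cycle_direct_cost(20, costs, eren, on_treatment = FALSE)
  expect_equal(c5e$resource - c5$resource, 5.89)
  # drug cost added only when on treatment
  con <- cycle_direct_cost(20, costs, eren, on_treatment = TRUE)
  expect_equal(con$total - c5e$total, drug_cost_per_cycle(eren, costs))
})

test_that("cycle QALYs are utility times year-fraction, floored at zero", {
  m <- utility_model(0.85, 0.0176)
  expect_equal(cycle_qaly(0, m), 0.85 * 84 / 365.25)
  expect_equal(round(cycle_qaly(0, m), 5), 0.19548)
  expect_equal(cycle_qaly(10, m, ae_decrement = 0),
               predict_utility(m, 10) * 84 / 365.25)
  # decrement larger than the utility cannot drive QALYs negative
  expect_equal(cycle_qaly(28, utility_model(0.4, 0.0176), ae_decrement = 1), 0)
})

test_that("accrual converts person-cycles at MMD into migraine days", {
  # single-cycle synthetic trace: 1 person-cycle at 10 MMD
  arm <- em$arms$intervention
  arm$ae_incidence <- list()
  trace <- data.frame(cycle = 0:1, weight = c(0, 1), age = c(41, 41),
                      on_treatment = c(1, 1), discontinued = c(0, 0),
                      dead = c(0, 0), alive = c(1, 1),
                      mmd_on = c(10, 10), mmd_disc = c(10, 10))
  res <- accrue(trace, em, arm)
  expect_equal(unname(res$totals["migraine_days"]), 10 * 84 / 30.4375)
  expect_equal(round(unname(res$totals["migraine_days"]), 2), 27.60)
})

test_that("a fully dead trace accrues nothing", {
  arm <- em$arms$intervention
  trace <- data.frame(cycle = 0:2, weight = c(0, 1, 1), age = 41:43,
                      on_treatment = 0, discontinued = 0, dead = c(0, 1, 1),
                      alive = 0, mmd_on = 5, mmd_disc = 5)
  res <- accrue(trace, em, arm)
  expect_equal(unname(res$totals["cost_discounted"]), 0)
  expect_equal(unname(res$totals["qalys_discounted"]), 0)
  expect_equal(unname(res$totals["migraine_days"]), 0)
})

test_that("total cost equals the sum of its categories, cycle by cycle", {
  run <- run_cea(em)
  for (res in list(run$intervention, run$comparator)) {
    pc <- res$cycles
    expect_equal(pc$cost_total,
                 pc$cost_drug + pc$cost_acute + pc$cost_resource +
                   pc$cost_indirect, tolerance = 1e-9)
    expect_equal(unname(res$totals["cost_discounted"]),
                 unname(res$totals["cost_drug_discounted"] +
                          res$totals["cost_acute_discounted"] +
                          res$totals["cost_resource_discounted"] +
                          res$totals["cost_indirect_discounted"]),
                 tolerance = 1e-9)
    expect_lte(unname(res$totals["cost_discounted"]),
               unname(res$totals["cost_undiscounted"]))
    expect_lte(unname(res$totals["qalys_discounted"]),
               unname(res$totals["qalys_undiscounted"]))
  }
})

test_that("totals weakly decrease as the discount rate increases", {
  prev_cost <- prev_qaly <- Inf
  for (r in c(0, 0.03, 0.05)) {
    p <- em
    p$settings$discount_rate_costs <- r
    p$settings$discount_rate_effects <- r
    run <- run_cea(p)
    cost <- unname(run$intervention$totals["cost_discounted"])
    qaly <- unname(run$intervention$totals["qalys_discounted"])
    expect_lte(cost, prev_cost)
    expect_lte(qaly, prev_qaly)
    prev_cost <- cost; prev_qaly <- qaly
  }
})

test_that("societal totals equal healthcare totals plus the indirect
           category, everything else unchanged", {
  soc <- em
  soc$settings$perspective <- "societal"
  r_h <- run_cea(em)
  r_s <- run_cea(soc)
  for (an in c("intervention", "comparator")) {
    th <- r_h[[an]]$totals; ts <- r_s[[an]]$totals
    expect_equal(unname(ts["cost_discounted"]),
                 unname(th["cost_discounted"] + ts["cost_indirect_discounted"]),
                 tolerance = 1e-9)
    expect_gt(unname(ts["cost_indirect_discounted"]), 0)
    for (cat in c("cost_drug_discounted", "cost_acute_discounted",
                  "cost_resource_discounted", "qalys_discounted",
                  "migraine_days"))
      expect_equal(unname(ts[cat]), unname(th[cat]), tolerance = 1e-12)
  }
})

test_that("incremental comparison handles ratios, dominance and guards", {
  topi <- arm_result(17059, 5.8839, 1049, "topiramate")
  eren <- arm_result(21479, 6.1150, 877, "erenumab")
  ce <- compare_arms(eren, topi)
  expect_equal(ce$delta_cost, 4420)
  expect_equal(ce$delta_qaly, 0.2311)
  expect_equal(ce$delta_md, 172)
  expect_equal(ce$icer_per_qaly, 4420 / 0.2311)
  expect_equal(ce$cost_per_md_avoided, 4420 / 172)
  expect_equal(ce$dominance, "none")

  dom <- compare_arms(arm_result(100, 2, 50), arm_result(200, 1, 80))
  expect_equal(dom$dominance, "intervention_dominant")
  expect_true(is.na(dom$icer_per_qaly))
  dominated <- compare_arms(arm_result(200, 1, 80), arm_result(100, 2, 50))
  expect_equal(dominated$dominance, "intervention_dominated")
  tie <- compare_arms(arm_result(200, 1, 50), arm_result(100, 1, 50))
  expect_true(is.na(tie$icer_per_qaly))
  expect_true(is.na(tie$cost_per_md_avoided))
})
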