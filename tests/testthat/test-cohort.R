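em <- default_parameters("EM")
cm <- default_parameters("CM")

test_that("annual-to-cycle probability conversion follows the closed form", {
  expect_equal(annual_to_cycle_prob(0, 84), 0)
  expect_equal(annual_to_cycle_prob(1, 84), 1)
  expect_equal(annual_to_cycle_prob(0.01, 84), 1 - 0.99^(84 / 365.25))
  expect_equal(annual_to_cycle_prob(0.01, 84), 0.002309, tolerance = 1e-3)
  expect_error(annual_to_cycle_prob(1.1, 84), "\\[0,1\\]")
})

test_that("a 10-year horizon splits into 43 full cycles plus a 0.482 partial", {
  hz <- horizon_cycles(em$settings)
  expect_equal(hz$n_cycles, 44)
  expect_equal(hz$weights[43], 1)
  expect_equal(hz$weights[44], 3652.5 / 84 - 43, tolerance = 1e-12)
  expect_equal(round(hz$weights[44], 3), 0.482)
  expect_equal(sum(hz$weights) * 84, 3652.5)
})

test_that("decision tree splits the cohort per response and AE discontinuation", {
  arm <- em$arms$intervention
  occ <- run_decision_tree(arm, em$population, life_table = NULL)
  expect_equal(occ$on_treatment, 0.37 * (1 - 0.0552))
  expect_equal(occ$on_treatment + occ$discontinued + occ$dead, 1)

  arm0 <- arm; arm0$response_prob <- 0
  expect_equal(run_decision_tree(arm0, em$population)$on_treatment, 0)
  arm1 <- arm; arm1$response_prob <- 1; arm1$ae_discontinuation_prob_cycle1 <- 0
  occ1 <- run_decision_tree(arm1, em$population, em$life_table)
  expect_equal(occ1$on_treatment, 1 - occ1$dead)
})

test_that("with no mortality the on-treatment state decays geometrically", {
  arm <- cm$arms$comparator  # placebo, long-term discontinuation 0.3026
  trace <- run_markov_trace(arm, cm$population, life_table = NULL,
                            settings = cm$settings)
  r1 <- trace$on_treatment[trace$cycle == 1]
  expect_equal(r1, 0.17 * (1 - 0.0071))
  k <- 2:43  # full cycles
  expect_equal(trace$on_treatment[trace$cycle %in% k],
               r1 * (1 - 0.3026)^(k - 1), tolerance = 1e-12)
  # partial final cycle uses the fractional-power survival
  w <- trace$weight[trace$cycle == 44]
  expect_equal(trace$on_treatment[trace$cycle == 44],
               r1 * 0.6974^42 * 0.6974^w, tolerance = 1e-12)
})

test_that("zero discontinuation and zero mortality freeze the trace after
           the assessment", {
  arm <- em$arms$intervention
  arm$longterm_discontinuation_prob_per_cycle <- 0
  trace <- run_markov_trace(arm, em$population, life_table = NULL,
                            settings = em$settings)
  on <- trace$on_treatment[trace$cycle >= 1]
  expect_equal(on, rep(on[1], length(on)))
  expect_equal(unique(trace$dead), 0)
})

test_that("occupancies conserve mass and mortality is monotone on
           randomized parameter sets", {
  set.seed(101)
  for (i in 1:8) {
    rp <- random_arm_population()
    trace <- run_markov_trace(rp$arm, rp$population, em$life_table,
                              em$settings)
    expect_equal(trace$on_treatment + trace$discontinued + trace$dead,
                 rep(1, nrow(trace)), tolerance = 1e-12)
    expect_true(all(diff(trace$dead) >= 0))
    expect_true(all(trace$on_treatment >= 0 & trace$discontinued >= 0))
    # a 10-year horizon never empties a mid-life cohort
    expect_gt(trace$alive[nrow(trace)], 0)
  }
})

test_that("cohort trace matches an individual-level microsimulation within
           Monte Carlo error", {
  set.seed(77)
  n_pat <- 2e5
  for (i in 1:5) {
    rp <- random_arm_population()
    trace <- run_markov_trace(rp$arm, rp$population, em$life_table,
                              em$settings)
    sim <- microsim_trace(rp$arm, rp$population, em$life_table, em$settings,
                          n_patients = n_pat, n_cycles = 43)
    for (col in c("on_treatment", "discontinued", "dead")) {
      p <- trace[[col]][match(sim$cycle, trace$cycle)]
      mc_se <- sqrt(pmax(p * (1 - p), 1e-12) / n_pat)
      expect_true(all(abs(sim[[col]] - p) <= 3 * mc_se + 1e-9),
                  info = sprintf("set %d, column %s", i, col))
    }
  }
})

test_that("responder MMD calibration reproduces the arm-average targets", {
  arm <- em$arms$intervention
  trace <- run_markov_trace(arm, em$population, em$life_table, em$settings)
  # forward-check each target cycle: occupancy-weighted mean over the
  # living equals the published arm average
  targets <- data.frame(cycle = c(1, 2, 9), mean = c(6.95, 7.23, 7.42))
  for (j in seq_len(nrow(targets))) {
    row <- trace[trace$cycle == targets$cycle[j], ]
    avg <- (row$on_treatment * row$mmd_on + row$discontinued * row$mmd_disc) /
      row$alive
    expect_equal(avg, targets$mean[j], tolerance = 1e-9)
  }
  expect_true(all(trace$mmd_on >= 0 & trace$mmd_on <= em$population$baseline_mmd))
})

test_that("degenerate and infeasible calibration targets behave as specified", {
  arm <- em$arms$intervention
  trace <- run_markov_trace(arm, em$population, em$life_table, em$settings)
  occ <- list(on = trace$on_treatment[-1], disc = trace$discontinued[-1])
  # targets equal to baseline -> responder MMD equals baseline
  cal <- calibrate_responder_mmd(arm, em$population, occ, em$settings,
                                 targets = list(weeks = 12,
                                                arm_mean_mmd = 9.44))
  expect_equal(cal$mmd_responder, rep(9.44, length(occ$on)))
  # an arm average far below what a small responder fraction can deliver
  arm_small <- arm; arm_small$response_prob <- 0.05
  trace_s <- run_markov_trace(arm_small, em$population, em$life_table,
                              em$settings,
                              mmd_assignment = list(
                                mmd_responder = rep(1, 44),
                                mmd_discontinued = 9.44))
  occ_s <- list(on = trace_s$on_treatment[-1], disc = trace_s$discontinued[-1])
  expect_error(
    calibrate_responder_mmd(arm_small, em$population, occ_s, em$settings,
                            targets = list(weeks = 12, arm_mean_mmd = 0.1)),
    "infeasible")
})

test_that("life-table lookups beyond the last age reuse the final row", {
  lt <- generate_life_table(0.001, 1.09, anchor_age = 41, max_age = 60)
  s <- em$settings
  s$horizon_years <- 30  # pushes the cohort past age 60
  trace <- run_markov_trace(em$arms$intervention, em$population, lt, s)
  expect_true(all(is.finite(trace$dead)))
  expect_true(all(diff(trace$dead) >= 0))
})
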