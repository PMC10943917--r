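em <- default_parameters("EM")

test_that("moment matching reproduces textbook parameterisations", {
  b <- moment_match("beta", 0.5, 0.1)
  expect_equal(b$alpha, 12)
  expect_equal(b$beta, 12)
  g <- moment_match("gamma", 2, 1)
  expect_equal(g$shape, 4)
  expect_equal(g$rate, 2)
  ln <- moment_match("lognormal", 2.76, 1.16)
  expect_equal(ln$sdlog^2, log(1 + 1.16^2 / 2.76^2))
  expect_equal(ln$meanlog, log(2.76) - ln$sdlog^2 / 2)
  # se = 0 degenerates to a point mass whatever the family
  f <- moment_match("lognormal", 2.27, 0)
  expect_equal(f$family, "fixed")
  expect_equal(f$draw(5), rep(2.27, 5))
  expect_error(moment_match("beta", 0.5, 0.6), "se\\^2")
  expect_error(moment_match("gamma", -1, 0.5), "> 0")
})

test_that("sampled moments match the targets within Monte Carlo error", {
  set.seed(9)
  n <- 50000
  cases <- list(list("beta", 0.3026, 0.0177), list("beta", 0.18, 0.02),
                list("gamma", 0.051, 0.0112), list("gamma", 227.7, 45),
                list("lognormal", 2.76, 1.16))
  for (cs in cases) {
    d <- moment_match(cs[[1]], cs[[2]], cs[[3]])
    x <- d$draw(n)
    expect_lt(abs(mean(x) - cs[[2]]), 3 * cs[[3]] / sqrt(n))
    # sd of the sample sd ~ se/sqrt(2(n-1)) for near-normal; allow a
    # generous factor for the skewed families
    expect_lt(abs(sd(x) - cs[[3]]), 6 * cs[[3]] / sqrt(n))
  }
})

test_that("odds-ratio transform maps comparator to intervention response", {
  expect_equal(response_from_odds_ratio(0.18, 2.76), 0.3773, tolerance = 1e-4)
  expect_equal(response_from_odds_ratio(0.3, 1), 0.3)
})

test_that("degenerate specs return the base set unchanged; sampled sets
           stay valid", {
  fixed <- lapply(default_psa_specs(em), function(sp) {
    if (identical(sp$family, "multivariate_normal"))
      sp$covariance <- sp$covariance * 0
    else sp$se <- 0
    sp
  })
  set.seed(4)
  p <- sample_parameter_set(em, fixed)
  expect_equal(p, em, tolerance = 1e-12)

  specs <- default_psa_specs(em)
  set.seed(5)
  for (i in 1:10) {
    q <- sample_parameter_set(em, specs)
    expect_length(validate_parameters(q), 0)
    # linked response: intervention p derived from sampled comparator p and OR
    pc <- q$arms$comparator$response_prob
    expect_equal(q$arms$intervention$response_prob,
                 response_from_odds_ratio(pc, q$arms$comparator$response_or))
  }
})

test_that("PSA is reproducible, degenerate PSA equals the deterministic
           run, and partitioned variance behaves", {
  specs <- default_psa_specs(em)
  p1 <- run_psa(em, specs, n_iterations = 20, seed = 123)
  p2 <- run_psa(em, specs, n_iterations = 20, seed = 123)
  expect_identical(p1$iterations, p2$iterations)
  # iteration i is independent of the total count
  p3 <- run_psa(em, specs, n_iterations = 10, seed = 123)
  expect_equal(p3$iterations, p1$iterations[1:10, ])

  fixed <- lapply(specs, function(sp) {
    if (identical(sp$family, "multivariate_normal"))
      sp$covariance <- sp$covariance * 0
    else sp$se <- 0
    sp
  })
  pf <- run_psa(em, fixed, n_iterations = 5, seed = 1)
  det <- run_cea(em)
  expect_equal(pf$iterations$delta_cost, rep(det$ce$delta_cost, 5))
  expect_equal(pf$iterations$delta_qaly, rep(det$ce$delta_qaly, 5))

  # costs-only uncertainty leaves the QALY difference constant
  cost_only <- fixed
  cost_only$unit_cost_hospitalisation <- specs$unit_cost_hospitalisation
  pc <- run_psa(em, cost_only, n_iterations = 5, seed = 2)
  expect_equal(pc$iterations$delta_qaly, rep(det$ce$delta_qaly, 5))
  expect_gt(sd(pc$iterations$delta_cost), 0)
})

test_that("CEAC definition, limits and hand-worked example", {
  it <- data.frame(delta_cost = c(100, -50), delta_qaly = c(0.01, 0.02))
  cv <- ceac(it, wtp_grid = c(10000, 20000))
  # at 10k: NMB = (0, 250) -> 0.5; at 20k: (100, 450) -> 1
  expect_equal(cv$prob_cost_effective, c(0.5, 1))
  # lambda = 0 counts cost-saving iterations
  expect_equal(ceac(it, c(0, 1))$prob_cost_effective[1], 0.5)
  # large lambda approaches the fraction with positive QALY gain
  it2 <- data.frame(delta_cost = rnorm(200, 0, 100),
                    delta_qaly = c(rep(0.1, 150), rep(-0.1, 50)))
  expect_equal(ceac(it2, c(0, 1e9))$prob_cost_effective[2], 0.75)
  # all dominant -> curve at 1 everywhere
  it3 <- data.frame(delta_cost = c(-10, -20), delta_qaly = c(0.1, 0.2))
  expect_true(all(ceac(it3, c(0, 30000, 1e6))$prob_cost_effective == 1))
  expect_true(all(ceac(it2)$prob_cost_effective >= 0 &
                    ceac(it2)$prob_cost_effective <= 1))
  expect_error(ceac(it, wtp_grid = 5), ">= 2")
})

test_that("tornado ranks influential parameters, caps probabilities, and is
           permutation-invariant", {
  paths <- c("utility/slope_per_mmd",
             "arms/intervention/response_prob",
             "costs/resources/primary_care_visit/unit_cost")
  tor <- tornado(em, paths)
  expect_equal(nrow(tor), 3)
  expect_true(all(diff(tor$range_width) <= 0))
  # a EUR ~75 unit cost used in one band moves NMB far less than the
  # QALY-side drivers
  expect_equal(tor$parameter[3], "costs/resources/primary_care_visit/unit_cost")
  expect_true(all(tor$parameter[1:2] %in% paths[1:2]))

  tor_rev <- tornado(em, rev(paths))
  expect_equal(tor_rev$range_width, tor$range_width)
  expect_equal(tor_rev$parameter, tor$parameter)

  # a parameter with no model influence has zero range: the comparator
  # drug price in a zero-price arm
  cm <- default_parameters("CM")
  t0 <- tornado(cm, "arms/comparator/drug_price_per_dose")
  expect_equal(t0$range_width, 0)

  p9 <- set_param(em, "arms/intervention/response_prob", 0.9)
  expect_warning(t9 <- tornado(p9, "arms/intervention/response_prob"),
                 "capped")
  expect_equal(t9$high_value, 1)
})

test_that("scenario overlays: identity, perspective partition, and WPAI
           variant", {
  base_run <- run_cea(em)
  hb <- run_scenario(em, "healthcare_base")
  expect_equal(hb$ce$delta_cost, base_run$ce$delta_cost)
  expect_equal(hb$ce$delta_qaly, base_run$ce$delta_qaly)

  soc <- run_scenario(em, "societal")
  # differs from base only through the indirect-cost category
  expect_equal(soc$ce$delta_qaly, base_run$ce$delta_qaly, tolerance = 1e-12)
  expect_equal(soc$ce$delta_md, base_run$ce$delta_md, tolerance = 1e-12)
  ind_delta <- unname(soc$intervention$totals["cost_indirect_discounted"] -
                        soc$comparator$totals["cost_indirect_discounted"])
  expect_equal(soc$ce$delta_cost, base_run$ce$delta_cost + ind_delta,
               tolerance = 1e-9)

  wpai <- run_scenario(em, "wpai_productivity")
  expect_false(isTRUE(all.equal(wpai$ce$delta_cost, soc$ce$delta_cost)))
  expect_equal(wpai$ce$delta_qaly, soc$ce$delta_qaly)

  expect_error(run_scenario(em, "not_registered"), "unknown scenario")
})
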