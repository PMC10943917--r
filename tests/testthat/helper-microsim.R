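# Individual-level microsimulation oracle for the cohort trace.
#
# Simulates n exchangeable patients through the same disease process the
# cohort engine models -- first-cycle mortality, the response/adverse-event
# split, then per-cycle competing death and long-term discontinuation --
# using binomial draws on state counts.  Kept deliberately independent of
# run_markov_trace(): transitions are drawn, not multiplied.
# Full cycles only (the trace's partial final cycle is excluded upstream).
microsim_trace <- function(arm, population, life_table, settings,
                           n_patients = 2e5, n_cycles) {
  cd <- settings$cycle_length_days
  q_at <- function(age) {
    a <- floor(age)
    look <- function(sx) {
      sub <- life_table[life_table$sex == sx, ]
      sub <- sub[order(sub$age), ]
      sub$qx[pmin(pmax(a - min(sub$age) + 1, 1), nrow(sub))]
    }
    qa <- population$fraction_female * look("F") +
      (1 - population$fraction_female) * look("M")
    1 - (1 - qa)^(cd / 365.25)
  }

  on <- disc <- dead <- integer(n_cycles)
  # cycle 1: deaths before the response split
  d1 <- rbinom(1, n_patients, q_at(population$start_age))
  alive <- n_patients - d1
  resp <- rbinom(1, alive, arm$response_prob)
  stay <- rbinom(1, resp, 1 - arm$ae_discontinuation_prob_cycle1)
  on[1] <- stay; disc[1] <- alive - stay; dead[1] <- d1

  lt <- arm$longterm_discontinuation_prob_per_cycle
  for (k in 2:n_cycles) {
    q <- q_at(population$start_age + (k - 1) * cd / 365.25)
    d_on <- rbinom(1, on[k - 1], q)
    d_disc <- rbinom(1, disc[k - 1], q)
    leavers <- rbinom(1, on[k - 1] - d_on, lt)
    on[k] <- on[k - 1] - d_on - leavers
    disc[k] <- disc[k - 1] - d_disc + leavers
    dead[k] <- dead[k - 1] + d_on + d_disc
  }
  data.frame(cycle = seq_len(n_cycles),
             on_treatment = on / n_patients,
             discontinued = disc / n_patients,
             dead = dead / n_patients)
}

# A randomized but valid arm/population pair for property tests.
random_arm_population <- function() {
  baseline <- runif(1, 5, 25)
  arm <- list(
    name = "random_arm",
    response_prob = runif(1, 0.05, 0.95),
    response_or = NULL, response_or_se = NULL,
    ae_discontinuation_prob_cycle1 = runif(1, 0, 0.4),
    longterm_discontinuation_prob_per_cycle = runif(1, 0, 0.35),
    longterm_discontinuation_se = 0.01,
    drug_price_per_dose = runif(1, 0, 300), doses_per_cycle = 3,
    is_placeholder_price = TRUE, hospital_dispensed = TRUE,
    ae_incidence = list(),
    mmd_targets = NULL)
  population <- list(label = "EM", start_age = sample(30:55, 1),
                     fraction_female = runif(1, 0.4, 0.9),
                     baseline_mmd = baseline)
  list(arm = arm, population = population)
}
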