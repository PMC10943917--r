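#' Convert an annual probability to a cycle probability
#'
#' Constant-hazard conversion: `1 - (1 - q)^(cycle_days / 365.25)`.
#'
#' @param q_annual annual probability in \[0, 1\]; vectorised.
#' @param cycle_days cycle length in days.
#' @return per-cycle probability.
#' @export
annual_to_cycle_prob <- function(q_annual, cycle_days) {
  if (any(q_annual < 0 | q_annual > 1))
    stop("annual probability must lie in [0,1]", call. = FALSE)
  1 - (1 - q_annual)^(cycle_days / 365.25)
}

#' Number of cycles and final-cycle weight for a horizon
#'
#' A 10-year horizon (3652.5 days) is not a whole number of 84-day
#' cycles: it is discretised as the full cycles that fit plus one final
#' partial cycle whose accrual (and transition intensity) is weighted by
#' the remaining fraction of a cycle.
#'
#' @param settings the `settings` component of a `cea_params` object.
#' @return list with `n_cycles` (total, including any partial final
#'   cycle) and `weights` (length `n_cycles`; 1 except possibly the last).
#' @export
horizon_cycles <- function(settings) {
  total_days <- settings$horizon_years * 365.25
  n_full <- floor(total_days / settings$cycle_length_days)
  frac <- total_days / settings$cycle_length_days - n_full
  if (n_full < 1 && frac == 0)
    stop("horizon shorter than one cycle", call. = FALSE)
  if (frac > 1e-9)
    list(n_cycles = n_full + 1L, weights = c(rep(1, n_full), frac))
  else
    list(n_cycles = as.integer(n_full), weights = rep(1, n_full))
}

# Sex-mixed annual mortality at a (possibly fractional) age: the life
# table is looked up at floor(age); ages beyond the table use its last row.
mixed_annual_qx <- function(life_table, age, fraction_female) {
  a <- floor(age)
  look <- function(sx) {
    sub <- life_table[life_table$sex == sx, ]
    sub <- sub[order(sub$age), ]
    idx <- pmin(pmax(a - min(sub$age) + 1, 1), nrow(sub))
    sub$qx[idx]
  }
  fraction_female * look("F") + (1 - fraction_female) * look("M")
}

#' Run the 12-week decision tree
#'
#' All patients start treatment; at the end of the assessment period
#' responders (a ≥50% MMD reduction) who have not discontinued for
#' adverse events remain on treatment, everyone else living moves to
#' discontinuation.  Deaths during the first cycle are taken from the
#' life table before the response split (mortality is independent of
#' state).
#'
#' @param arm arm specification.
#' @param population population specification (`start_age`,
#'   `fraction_female`, `baseline_mmd`).
#' @param life_table data frame `age,sex,qx`; `NULL` for no mortality.
#' @param cycle_days cycle length in days.
#' @return list of cycle-1 occupancies: `on_treatment`, `discontinued`,
#'   `dead` (fractions summing to 1).
#' @export
run_decision_tree <- function(arm, population, life_table = NULL,
                              cycle_days = 84) {
  q1 <- if (is.null(life_table)) 0 else
    annual_to_cycle_prob(
      mixed_annual_qx(life_table, population$start_age,
                      population$fraction_female),
      cycle_days)
  alive <- 1 - q1
  on_treatment <- alive * arm$response_prob *
    (1 - arm$ae_discontinuation_prob_cycle1)
  list(on_treatment = on_treatment,
       discontinued = alive - on_treatment,
       dead = q1)
}

#' Run the Markov cohort trace
#'
#' Cycle 1 is the decision tree; from cycle 2 onward patients on
#' treatment leave for discontinuation at the arm's long-term per-cycle
#' probability, and both living states are exposed to background
#' mortality (sex-mixed life-table `qx` at the cohort's current age,
#' converted to the cycle length).  Discontinuation absorbs every exit
#' except death.  The final partial cycle uses transition probabilities
#' rescaled to its length.
#'
#' @inheritParams run_decision_tree
#' @param mmd_assignment `NULL` (calibrate from the arm's `mmd_targets`;
#'   see [calibrate_responder_mmd()]) or a list with `mmd_responder`
#'   (length `n_cycles`) and `mmd_discontinued` (scalar).
#' @param settings the `settings` component of a `cea_params` object.
#' @return a `cohort_trace` data frame, one row per cycle `0..n_cycles`:
#'   occupancies (`on_treatment`, `discontinued`, `dead`, `alive`),
#'   `weight` (accrual weight; 0 for the pre-assessment row 0), `age`,
#'   and the MMD attached to each living state (`mmd_on`, `mmd_disc`).
#' @export
run_markov_trace <- function(arm, population, life_table, settings,
                             mmd_assignment = NULL) {
  hz <- horizon_cycles(settings)
  K <- hz$n_cycles
  cd <- settings$cycle_length_days

  on <- disc <- dead <- numeric(K + 1)
  on[1] <- 1; disc[1] <- 0; dead[1] <- 0   # row 0: cohort entry
  age0 <- population$start_age
  ages <- age0 + (seq_len(K) - 1) * cd / 365.25

  tree <- run_decision_tree(arm, population, life_table, cycle_days = cd)
  on[2] <- tree$on_treatment; disc[2] <- tree$discontinued
  dead[2] <- tree$dead

  lt_disc <- arm$longterm_discontinuation_prob_per_cycle
  for (k in seq_len(K)[-1]) {
    w <- hz$weights[k]
    q <- if (is.null(life_table)) 0 else
      annual_to_cycle_prob(
        mixed_annual_qx(life_table, ages[k], population$fraction_female),
        cd * w)
    d_k <- if (w < 1) 1 - (1 - lt_disc)^w else lt_disc
    i <- k + 1
    on[i]   <- on[i - 1] * (1 - q) * (1 - d_k)
    disc[i] <- disc[i - 1] * (1 - q) + on[i - 1] * (1 - q) * d_k
    dead[i] <- dead[i - 1] + (on[i - 1] + disc[i - 1]) * q
  }

  if (is.null(mmd_assignment))
    mmd_assignment <- calibrate_responder_mmd(
      arm, population,
      occupancy = list(on = on[-1], disc = disc[-1]),
      settings = settings)

  trace <- data.frame(
    cycle = 0:K,
    weight = c(0, hz$weights),
    age = c(age0, ages),
    on_treatment = on,
    discontinued = disc,
    dead = dead,
    alive = on + disc,
    mmd_on = c(population$baseline_mmd, mmd_assignment$mmd_responder),
    mmd_disc = c(population$baseline_mmd,
                 rep(mmd_assignment$mmd_discontinued, K)))
  class(trace) <- c("cohort_trace", "data.frame")
  attr(trace, "arm_name") <- arm$name
  trace
}

#' Calibrate per-state responder MMD from arm-average targets
#'
#' The published trajectories are arm averages (responders and
#' non-responders pooled); the state-level MMD attached to responders is
#' recovered by inverting
#' \eqn{\bar m = p_{on} m_{resp} + (1 - p_{on}) m_{base}}
#' at each target timepoint, where \eqn{p_{on}} is the on-treatment
#' fraction among the living at that cycle and non-responders /
#' discontinuers sit at baseline MMD (the reversion convention).
#' Responder MMD is piecewise constant between targets (last target
#' carried forward).
#'
#' @param arm arm specification carrying `mmd_targets` (`weeks`,
#'   `arm_mean_mmd`).
#' @param population population specification.
#' @param occupancy list with per-cycle vectors `on` and `disc`
#'   (cycles 1..K).
#' @param settings model settings.
#' @param targets optional override of `arm$mmd_targets`.
#' @return list with `mmd_responder` (length K) and `mmd_discontinued`.
#' @export
calibrate_responder_mmd <- function(arm, population, occupancy, settings,
                                    targets = NULL) {
  K <- length(occupancy$on)
  baseline <- population$baseline_mmd
  targets <- targets %||% arm$mmd_targets
  if (is.null(targets)) {
    # no published trajectory: fall back on the responder definition
    # (>= 50% MMD reduction) at its boundary
    return(list(mmd_responder = rep(baseline / 2, K),
                mmd_discontinued = baseline))
  }
  weeks <- targets$weeks
  means <- targets$arm_mean_mmd
  if (any(means < 0 | means > 28))
    stop("arm-average MMD targets must lie in [0,28]", call. = FALSE)
  cycles <- pmin(pmax(round(weeks * 7 / settings$cycle_length_days), 1), K)
  m_resp <- numeric(length(cycles))
  for (j in seq_along(cycles)) {
    k <- cycles[j]
    alive <- occupancy$on[k] + occupancy$disc[k]
    p_on <- occupancy$on[k] / alive
    if (p_on <= 0)
      stop(sprintf(paste0("target %.2f MMD at week %g is infeasible: no ",
                          "patients remain on treatment at cycle %d"),
                   means[j], weeks[j], k), call. = FALSE)
    m <- (means[j] - (1 - p_on) * baseline) / p_on
    if (m < -1e-9 || m > baseline + 1e-9)
      stop(sprintf(paste0("target %.2f MMD at week %g is infeasible: implied ",
                          "responder MMD %.3f outside [0, baseline %.2f]"),
                   means[j], weeks[j], m, baseline), call. = FALSE)
    m_resp[j] <- min(max(m, 0), baseline)
  }
  step <- findInterval(seq_len(K), cycles)
  mmd_responder <- m_resp[pmax(step, 1)]
  list(mmd_responder = mmd_responder, mmd_discontinued = baseline)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
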