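---
title: "Methods: a decision-tree/Markov model for preventive migraine treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a decision-tree/Markov model for preventive migraine treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrainecea)
```

## The model

`migrainecea` implements a cohort-level cost-effectiveness model for
preventive migraine treatment, built for two comparisons: erenumab versus
topiramate in episodic migraine (EM, baseline 9.44 monthly migraine days,
MMD) and erenumab versus placebo on top of best supportive care in
chronic migraine (CM, baseline 18.66 MMD). A hypothetical cohort (age 41,
80.5% female) enters treatment, and a decision tree at the 12-week
assessment splits it into responders (≥50% MMD reduction) and
non-responders. Responders who have not stopped for adverse events stay
in the *treatment* state; everyone else living moves to
*discontinuation*, which also absorbs later treatment exits. From cycle 2
onward a constant per-cycle long-term discontinuation probability moves
patients off treatment, and both living states face background mortality
from a life table (sex-mixed `qx` at the cohort's current age, converted
to the 84-day cycle by `1-(1-q)^(84/365.25)`); mortality is not
migraine-related, so death is simply an absorbing exit from either state.

Key structural conventions:

* **Horizon discretisation.** Ten years (3652.5 days) is not a whole
  number of 12-week cycles; we run 43 full cycles plus a final partial
  cycle whose transition probabilities and accrual are scaled by the
  remaining fraction (0.482).
* **No half-cycle correction.** Costs and utilities attach to the state
  and MMD level at the end of each cycle, which is also why cycle 1 uses
  the post-assessment occupancies.
* **Drug exposure in cycle 1.** Everyone is on drug during the
  assessment period, so the full living cohort accrues one cycle of drug
  cost in cycle 1; thereafter only the treatment state does.
* **Reversion convention.** Non-responders and discontinuers sit at
  baseline MMD, accrue no preventive-drug cost, and keep the acute
  medication and resource use of their MMD band. This is a modelling
  convention — post-discontinuation MMD is not reported anywhere — and it
  is exposed as a parameter (`mmd_discontinued`) rather than hard-coded.

## MMD drives everything

Utilities come from a linear model fitted to (synthetic) patient-level
data: utility `= 0.85 − 0.0176 × MMD` (decrement SE 0.0035), clamped to
[0, 1]. At the extremes this gives 0.85 at 0 MMD and 0.3572 at 28 MMD.
The published per-band utility ranges are descriptive summaries of the
same line; where they disagree with the line by a point or two in the
second decimal we treat the linear model as normative. Adverse events
subtract an incidence-weighted catalogue disutility (e.g. constipation
0.029, brain fog 0.097) **once**, in the assessment cycle, pro-rated to
the cycle length. Whether the source analysis applied these per cycle or
once is not stated; recurring application would double-count what are
assessment-period incidences, so the one-off reading is the default.

Direct costs use five MMD bands (0, 1–3, 4–7, 8–14, 15+; fractional MMD
floors to its band). Each band carries a resource-use row (unit cost ×
units × fraction of patients per 12 weeks: hospitalisation €2,044.61,
emergency visit €227.70, GP €74.87, neurologist €104.36, pharmacy visit
€5.89 — the last only in arms on a hospital-dispensed drug) and an
acute-medication cost taken as the midpoint of the published band range
(the endpoints feed the tornado instead). The unit/percentage pairing of
the typeset resource table is ambiguous in places; the reconstruction
used here is stored in the config so users can override it.

Indirect costs (societal perspective only) value absenteeism days at a
full day of labour and presenteeism days at half a day, with the daily
labour cost `wage/working days × (1 − unemployment)` =
`2847.10/22 × 0.873 ≈ €112.98`. The wage is divided by working days
first; the source text states only that the unemployment rate was
"considered", and this order scales expected earnings per calendar
worker. Work-loss day counts per 3 months are linear in MMD and rescaled
by 84/90 to the cycle.

Migraine days accrue undiscounted (`MMD × 84/30.4375` per person-cycle);
costs and QALYs are discounted at 3%/year via
`(1+r)^(−k·84/365.25)`. The undiscounted-MD convention keeps the
MD-avoided outcome a raw count, consistent with the published integer
totals.

## Calibration of responder MMD

Published MMD trajectories are arm averages over responders and
non-responders pooled. The state-level responder MMD is recovered by
inverting `arm_avg = p_on·m_resp + (1−p_on)·baseline` at each target
timepoint, with `p_on` the on-treatment fraction among the living from
the trace (occupancies do not depend on MMD, so this is a single forward
pass plus a linear solve), and held piecewise constant between targets.
For EM both arms have targets at weeks 12, 24 and 108. For CM only
10-year endpoint means are available (13.48 erenumab, 18.32 placebo);
the placebo value cannot be inverted at year 10 because, at a
discontinuation probability of 0.3026/cycle, essentially nobody remains
on placebo "treatment" there. The packaged defaults therefore anchor
placebo at week 12 and erenumab at week 520, which reproduces both
endpoint means through the reversion convention. Infeasible targets
(implied responder MMD outside `[0, baseline]`) raise an error naming
the target.

In the sensitivity analyses the responder-MMD trajectory is calibrated
once on the base case and then held fixed: it is a structural input, and
re-inverting it per draw would let a sampled discontinuation probability
silently re-define what "responder" means (and fail outright for draws
that empty the treatment state before a target).

## Sensitivity analysis

* **Tornado**: each registered parameter at 0.8×/1.2× base
  (probabilities capped at 1 with a warning), outcome = net monetary
  benefit at €30,000/QALY by default (the ICER flips sign unstably when
  ΔQALY crosses 0), entries sorted by range.
* **Scenarios**: `healthcare_base`, `societal`, `wpai_productivity`
  (societal with WPAI-calibrated work-loss slopes), `no_discounting` —
  each a pure parameter overlay over an unchanged engine.
* **PSA**: beta for probabilities and AE disutilities, gamma for
  discontinuation and resource unit costs, lognormal for the odds
  ratio, (multivariate) normal for the utility coefficients, all
  moment-matched to (mean, SE). Published SEs are used where they
  exist (OR 1.16 for EM and 0.00 — i.e. fixed — for CM; long-term
  discontinuation 0.0112/0.0177; the AE disutility catalogue); where
  none is published the spec defaults to 20% of the mean, and the
  comparator response probability gets a binomial SE at an effective
  n of 500. These two conventions are analyst choices, adjustable per
  entry. The intervention response is re-derived from the sampled
  comparator response and odds ratio on the odds scale; when neither
  moved, the printed intervention probability is kept, so a fully
  degenerate PSA reproduces the deterministic result exactly. One root
  seed spawns an independent child seed per iteration, making iteration
  *i* reproducible regardless of the total count. The CEAC reports, per
  willingness-to-pay λ on a €0–50,000 grid (€100 steps), the fraction
  of iterations with `λ·ΔQALY − ΔCost > 0`.

Sampled probabilities are clamped to [0, 1] and the sampled utility
line is kept admissible (`intercept − 28·slope ≥ 0`); correlation
between the sampled response probability and the odds ratio is not
modelled (none is published).

## What the synthetic data emulate — and what they do not

No patient-level data from the source trials are public, so the
generator produces cohorts with exactly the structure the analysis
assumes: truncated-normal MMD on [0, 28]; utility linear in MMD with
truncated Gaussian noise; MIDAS absent days and presenteeism days as
negative-binomial counts (size 8) around means linear in MMD —
overdispersed nonnegative integers, which is why the work-loss fits use
heteroskedasticity-consistent (HC1) standard errors; Bernoulli
adverse-event flags. It does **not** emulate trial dropout, visit
schedules, EQ-5D scoring mechanics, or any nonlinearity in the
utility–MMD relationship. Tests that pass on these data therefore
validate the estimation and accrual machinery, not the clinical inputs:
a real re-analysis would substitute trial data and a national life
table (any `age,sex,qx` CSV drops in; the packaged one is synthetic,
Gompertz-like with 9%/year growth from 0.001 at age 41).

The work-loss coefficient defaults (absenteeism 0.25 + 0.45·MMD days
per 3 months; presenteeism 0.50 + 0.55·MMD, with a steeper 0.80 WPAI
variant) are the package's own calibration: they give indirect-cost
magnitudes of the order reported for these populations, but the source
regressions are unpublished.

## Placeholder drug prices

Reimbursed Spanish prices are confidential; the packaged defaults
(erenumab €160/dose, 3 doses/cycle; topiramate €8; both net of a
configurable 7.5% statutory discount) are placeholders flagged
`is_placeholder_price`, and every runner warns when they are in effect.
Absolute cost totals and ICERs computed from the defaults illustrate the
machinery; incremental *structure* (dominance under the societal
perspective, the ranking of tornado drivers, CEAC shape) is robust to
the price level, which the acceptance tests exploit.

## Numerical choices and degenerate inputs

* Occupancy conservation is maintained to 1e-12 per cycle and asserted
  in tests.
* `validate_parameters()` is total: it returns a violation report (one
  entry per problem, naming the key) for any parseable input and never
  throws; `assert_valid_parameters()` is the throwing wrapper used at
  API boundaries.
* Utilities clamp to [0, 1]; QALY accrual floors at 0 even when an AE
  decrement exceeds the state utility.
* Life-table lookups floor the (continuously advanced) age and reuse
  the last row beyond the table's maximum age.
* Beta moment-matching requires `se² < mean(1−mean)`; infeasible AE
  disutility SEs are clamped to the largest feasible value.
* A zero-variance spec in any family degenerates to a point mass.

## Problem sizes used in the tests

The suite validates the trace against a 200,000-patient individual-level
microsimulation on 5 randomised parameter sets (agreement within 3
Monte Carlo standard errors per state and cycle), recovers the utility
and absenteeism slopes across 200 synthetic replicates of n = 500
(95% CI coverage required in 93–97%), checks sampler moments on 50,000
draws per family, and exercises the PSA at 5–20 iterations where the
full 1000-iteration run (the default, used in
`analysis/04_sensitivity.R`) would add nothing to the property being
checked.

## Known limitations

* Two living states only: no treatment switching, re-challenge, or
  individual-level heterogeneity in the production path (the
  microsimulation exists purely as a test oracle).
* AE disutilities applied once; if the source applied them per cycle,
  QALY totals shift by a few thousandths.
* The Table-2 unit/percentage reconstruction and the CM calibration
  anchoring are conventions, documented above and overridable in
  config.
* No out-of-pocket or caregiver costs, no value-of-information outputs,
  no currency conversion or inflation machinery beyond a scalar
  multiplier.
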