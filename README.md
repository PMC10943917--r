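# migrainecea

Cost-effectiveness modelling of preventive migraine treatment in R: a
12-week decision tree feeding a two-state Markov cohort model
(on-treatment responders vs discontinuation, with background mortality)
over a 10-year horizon, in 84-day cycles.

The package is built around two base-case comparisons for adults (age
41, 80.5% female) with prior preventive-treatment failures:

* **Episodic migraine (EM)** — erenumab (response 37%) vs topiramate
  (response 18%, OR 2.76), baseline 9.44 monthly migraine days (MMD);
* **Chronic migraine (CM)** — erenumab (response 42%) vs placebo
  (response 17%, OR 2.27) on best supportive care, baseline 18.66 MMD.

Monthly migraine days drive both effects and costs:

* utility `u(MMD) = 0.85 − 0.0176·MMD`, clamped to [0, 1], with an
  incidence-weighted adverse-event disutility applied once at the
  assessment;
* direct costs by MMD band (0 / 1–3 / 4–7 / 8–14 / 15+) from
  resource-use tables plus acute medication and the preventive drug;
* indirect costs (societal perspective) from absenteeism/presenteeism
  regressions valued at `2847.10/22 × (1 − 0.127) ≈ €112.98` per day.

Per-arm discounted (3%/yr) costs and QALYs and undiscounted migraine
days (MD) are compared as an incremental cost-effectiveness ratio
(ICER, €/QALY) and cost per MD avoided, against a €30,000/QALY
threshold. One-way ±20% tornado analysis, scenario overlays and a
probabilistic sensitivity analysis (beta/gamma/lognormal/multivariate
normal, moment-matched) with cost-effectiveness acceptability curves
are built in, as is a synthetic patient-level data generator so every
regression and validation step runs without any external download.

**Drug prices are placeholders** (reimbursed prices are confidential);
every runner warns while they are in effect. Absolute cost totals with
the defaults illustrate the machinery, not a pricing conclusion.

## Worked example

```r
library(migrainecea)

params <- default_parameters("EM")
run <- run_cea(params)
run
#> <arm_result> erenumab
#>   cost (disc.)  EUR   19974.27
#>   QALYs (disc.)     6.1598
#>   migraine days      896.9
#> <arm_result> topiramate
#>   cost (disc.)  EUR   16226.32
#>   QALYs (disc.)     5.9171
#>   migraine days     1084.3
#> <ce_result> erenumab vs topiramate
#>   incremental cost  EUR    3747.95
#>   incremental QALYs     0.2427
#>   MDs avoided            187.5
#>   ICER              EUR      15445 /QALY
#>   cost per MD avoided EUR    19.99
#>   NMB at EUR 30000/QALY: 3532
```

Over 10 years the erenumab cohort accrues 0.24 extra QALYs and avoids
188 migraine days per patient; at the placeholder price premium the
extra €3,748 gives an ICER of ~€15,400/QALY, well under the €30,000
threshold. Switching to the societal perspective adds productivity
costs and makes erenumab dominant (cheaper *and* more effective):

```r
run_scenario(params, "societal")$ce$dominance
#> [1] "intervention_dominant"
```

Incremental arithmetic on externally given per-arm totals uses the same
comparison operation:

```r
compare_arms(arm_result(21479, 6.1150, 877,  "erenumab"),
             arm_result(17059, 5.8839, 1049, "topiramate"))
#> <ce_result> erenumab vs topiramate
#>   incremental cost  EUR    4420.00
#>   incremental QALYs     0.2311
#>   MDs avoided            172.0
#>   ICER              EUR      19126 /QALY
#>   cost per MD avoided EUR    25.70
#>   NMB at EUR 30000/QALY: 2513
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
full analysis, writing tables under `results/`:

| script | what it does |
|---|---|
| `01_synthetic_trial.R` | synthetic patient-level trial + life table |
| `02_fit_models.R` | utility and work-loss regressions, recovery check |
| `03_base_case.R` | EM and CM base-case runs, both perspectives |
| `04_sensitivity.R` | tornado, scenarios, 1000-iteration PSA + CEAC |

Run them in order from the repository root, e.g.
`Rscript analysis/01_synthetic_trial.R`.

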