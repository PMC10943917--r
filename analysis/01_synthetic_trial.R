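#!/usr/bin/env Rscript
# Step 1 -- synthetic trial-like data.
#
# No patient-level trial data are public, so every downstream fit runs on
# synthetic cohorts with the structure the analysis assumes: utility
# linear in monthly migraine days (intercept 0.85, decrement 0.0176/MMD),
# MIDAS absent days and presenteeism days as overdispersed counts with
# means linear in MMD, adverse-event flags at arm-level incidences.

library(migrainecea)

out_dir <- "results/01_synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

spec <- synth_spec(
  n_patients = 5000,
  true_utility_intercept = 0.85, true_utility_slope = 0.0176,
  utility_noise_sd = 0.08,
  true_absenteeism_intercept = 0.25, true_absenteeism_slope = 0.45,
  true_presenteeism_intercept = 0.50, true_presenteeism_slope = 0.55,
  mmd_mean = 9.44, mmd_sd = 6,
  ae_incidence = list(constipation = 0.064, injection_site_pain = 0.056),
  rng_seed = 20240315)

patients <- write_synthetic_dataset(spec, out_dir)

cat(sprintf("wrote %d synthetic patients to %s\n", nrow(patients), out_dir))
cat(sprintf("  MMD: mean %.2f (sd %.2f), range [%.1f, %.1f]\n",
            mean(patients$mmd), sd(patients$mmd),
            min(patients$mmd), max(patients$mmd)))
cat(sprintf("  observed utility: mean %.3f\n", mean(patients$utility_observed)))
cat(sprintf("  MIDAS absent days / 3 months: mean %.2f\n",
            mean(patients$midas_days_absent)))
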