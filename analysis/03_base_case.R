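#!/usr/bin/env Rscript
# Step 3 -- base-case cost-effectiveness runs.
#
# Episodic migraine (erenumab vs topiramate) and chronic migraine
# (erenumab vs placebo) over 10 years from the healthcare perspective,
# with the packaged parameter defaults.  Drug prices are placeholders
# (confidential reimbursed prices are not public), so the absolute cost
# and ICER figures here illustrate the machinery rather than reproduce
# the published headline numbers.

library(migrainecea)

for (lab in c("EM", "CM")) {
  out_dir <- file.path("results/03_base_case", tolower(lab))
  params <- default_parameters(lab)
  run <- suppressWarnings(run_cea_files(params, out_dir))
  cat(sprintf("\n=== %s (%s vs %s), healthcare perspective ===\n",
              lab, run$intervention$label, run$comparator$label))
  print(run)
  # societal perspective as a scenario
  soc <- run_scenario(params, "societal")
  cat(sprintf("societal: delta cost %.0f EUR, NMB %.0f EUR\n",
              soc$ce$delta_cost, soc$ce$nmb))
  if (soc$ce$dominance == "intervention_dominant")
    cat("societal perspective: intervention dominant (cheaper and more effective)\n")
}
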