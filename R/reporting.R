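#' Write a run manifest
#'
#' Every results directory is self-describing: the manifest records the
#' seed, package version, timestamp, scenario and a stable hash of the
#' resolved parameters, and is written before any result table.
#'
#' @param out_dir output directory (created if needed).
#' @param params resolved `cea_params` object.
#' @param seed integer seed in effect.
#' @param scenario scenario name, if any.
#' @return the manifest as a list, invisibly; written to
#'   `manifest.json` in `out_dir`.
#' @export
write_manifest <- function(out_dir, params, seed = params$settings$rng_seed,
                           scenario = "base") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "migrainecea",
    version = as.character(utils::packageVersion("migrainecea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    scenario = scenario,
    population = params$population$label,
    perspective = params$settings$perspective,
    parameter_hash = rlang::hash(unclass(params)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

placeholder_price_warning <- function(params) {
  ph <- vapply(params$arms, function(a) isTRUE(a$is_placeholder_price),
               logical(1))
  if (any(ph))
    warning("placeholder drug price(s) in arm(s): ",
            paste(names(params$arms)[ph], collapse = ", "),
            "; headline ICERs are price-dependent", call. = FALSE)
  invisible(any(ph))
}

#' Run the base-case analysis and write result files
#'
#' Writes, under `out_dir`: `manifest.json`, the resolved configuration,
#' per-arm cohort traces, per-arm totals and the incremental comparison,
#' all as delimited text.
#'
#' @param params a `cea_params` object (or a config path).
#' @param out_dir output directory.
#' @return the `cea_run`, invisibly.
#' @export
run_cea_files <- function(params, out_dir) {
  if (is.character(params)) params <- load_config(params)
  assert_valid_parameters(params)
  placeholder_price_warning(params)
  write_manifest(out_dir, params)
  resolved <- file.path(out_dir, "parameters_resolved.yaml")
  write_config(params, resolved)
  # the resolved config is the canonical input: running from what was
  # written makes a rerun from this directory byte-identical
  params <- load_config(resolved)
  run <- run_cea(params, validate = FALSE)
  for (an in c("intervention", "comparator")) {
    utils::write.csv(run$traces[[an]],
                     file.path(out_dir, paste0("trace_", an, ".csv")),
                     row.names = FALSE)
    utils::write.csv(run[[an]]$cycles,
                     file.path(out_dir, paste0("accrual_", an, ".csv")),
                     row.names = FALSE)
  }
  totals <- data.frame(
    arm = c(run$intervention$label, run$comparator$label),
    rbind(run$intervention$totals, run$comparator$totals))
  utils::write.csv(totals, file.path(out_dir, "arm_totals.csv"),
                   row.names = FALSE)
  ce <- run$ce
  utils::write.csv(
    data.frame(intervention = ce$intervention, comparator = ce$comparator,
               delta_cost = ce$delta_cost, delta_qaly = ce$delta_qaly,
               delta_md = ce$delta_md, icer_per_qaly = ce$icer_per_qaly,
               cost_per_md_avoided = ce$cost_per_md_avoided,
               nmb = ce$nmb, dominance = ce$dominance),
    file.path(out_dir, "ce_result.csv"), row.names = FALSE)
  invisible(run)
}

#' Run the PSA and write result files
#'
#' Writes `manifest.json`, the per-iteration incremental outcomes and
#' the CEAC grid under `out_dir`.
#'
#' @inheritParams run_cea_files
#' @param n_iterations,seed forwarded to [run_psa()].
#' @return the `psa_result`, invisibly.
#' @export
run_psa_files <- function(params, out_dir, n_iterations = NULL, seed = NULL) {
  if (is.character(params)) params <- load_config(params)
  assert_valid_parameters(params)
  placeholder_price_warning(params)
  seed <- seed %||% params$settings$rng_seed
  write_manifest(out_dir, params, seed = seed, scenario = "psa")
  psa <- run_psa(params, n_iterations = n_iterations, seed = seed)
  utils::write.csv(psa$iterations, file.path(out_dir, "psa_iterations.csv"),
                   row.names = FALSE)
  utils::write.csv(psa$ceac, file.path(out_dir, "ceac.csv"),
                   row.names = FALSE)
  invisible(psa)
}

#' Generate and write a synthetic dataset
#'
#' Writes the patient-level table, a synthetic life table and the
#' generator spec used, under `out_dir`.
#'
#' @param spec a [synth_spec()].
#' @param out_dir output directory.
#' @return the patient table, invisibly.
#' @export
write_synthetic_dataset <- function(spec, out_dir) {
  validate_synth_spec(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d <- generate_trial(spec)
  utils::write.csv(d, file.path(out_dir, "synthetic_patients.csv"),
                   row.names = FALSE)
  write_life_table(generate_life_table(),
                   file.path(out_dir, "lifetable_synthetic.csv"))
  yaml::write_yaml(unclass(spec), file.path(out_dir, "generator_spec.yaml"))
  invisible(d)
}
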