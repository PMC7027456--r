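#' Run the full facility pipeline for one configuration
#'
#' Executes upstream sizing, per-batch downstream propagation, scheduling
#' and the cost rollup for a scenario configuration, returning everything a
#' facility report needs.
#'
#' @param config A [scenario_config()] (or a config read from file).
#' @return Object of class `tea_run` with elements `config`, `plan`
#'   (upstream plan), `records` (chain stage records), `quality`
#'   ([quality_metrics()]), `schedule` ([make_schedule()]) and `report`
#'   ([cost_report()]).
#' @examples
#' run <- run_pipeline(scenario_config("base"))
#' run$report
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "tea_config"))
  plan <- upstream_plan(config$host, config$demand_kg,
                        config$overall_recovery, config$batches,
                        config$prices$seeds_per_g, config$prices$seed_per_g)
  harvest <- harvest_stream(plan$fw_per_batch_kg, config$host)
  records <- run_chain(config$chain, harvest)
  quality <- quality_metrics(records)
  sched <- make_schedule(
    schedule_inputs(config$schedule$operating_days_per_year,
                    config$schedule$upstream_cycle_days,
                    config$schedule$downstream_cycle_days,
                    requested_batches = config$batches),
    plan$plants_per_batch)
  report <- cost_report(config$equipment, config$ledger, config$demand_kg)
  structure(list(config = config, plan = plan, records = records,
                 quality = quality, schedule = sched, report = report),
            class = "tea_run")
}

#' @export
print.tea_run <- function(x, ...) {
  cat(sprintf("<tea_run> scenario '%s' (%s)\n", x$config$scenario,
              x$config$host$name))
  cat(sprintf("  %.4g kg FW/batch -> %.3f kg powder/batch (%.2f kg AMP, %.1f%% purity)\n",
              x$plan$fw_per_batch_kg,
              x$quality$formulated_mass_per_batch_kg,
              x$quality$amp_mass_per_batch_kg,
              x$quality$protein_basis_purity_pct))
  print(x$report)
  invisible(x)
}

#' Run a named facility scenario end to end
#'
#' Convenience wrapper: builds the scenario fixture configuration and runs
#' the full pipeline.
#'
#' @param name `"base"`, `"spinach"` or `"tobacco"`.
#' @return A `tea_run` (see [run_pipeline()]).
#' @export
run_scenario <- function(name = c("base", "spinach", "tobacco")) {
  name <- match.arg(name)
  run_pipeline(scenario_config(name))
}
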