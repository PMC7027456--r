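#' Write the scenario reports for a pipeline run
#'
#' Emits the scenario summary (CAPEX/OPEX/COGS by section), the stage-by-
#' stage batch table, the cost ledger breakdown and the schedule, each as
#' both JSON and an aligned text/CSV file, plus a run manifest listing every
#' output with its checksum.
#'
#' @param run A `tea_run` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return Object of class `tea_run_manifest`; errors if the directory
#'   cannot be written.
#' @export
write_reports <- function(run, outdir) {
  stopifnot(inherits(run, "tea_run"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir,
                                call. = FALSE)
  files <- character(0)
  emit_json <- function(obj, name) {
    p <- file.path(outdir, name)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    files <<- c(files, p)
    p
  }
  emit_text <- function(lines, name) {
    p <- file.path(outdir, name)
    writeLines(lines, p)
    files <<- c(files, p)
    p
  }

  summ <- summary_table(run$report)
  emit_json(summ, "summary.json")
  emit_text(c(sprintf("Scenario: %s (%s)", run$config$scenario,
                      run$config$host$name),
              utils::capture.output(print(summ, row.names = FALSE))),
            "summary.txt")

  stages <- batch_report(run$records)
  if (NROW(stages)) {
    p <- file.path(outdir, "stage_table.csv")
    utils::write.csv(stages, p, row.names = FALSE)
    files <- c(files, p)
    emit_json(stages, "stage_table.json")
    stage_note <- NULL
  } else {
    stage_note <- "stage table omitted: empty stage list"
  }

  ledger <- run$report$opex$items
  p <- file.path(outdir, "ledger.csv")
  utils::write.csv(ledger, p, row.names = FALSE)
  files <- c(files, p)
  emit_json(ledger, "ledger.json")

  emit_json(list(batches_per_year = run$schedule$batches_per_year,
                 stagger_days = run$schedule$stagger_days,
                 concurrent_growth_batches =
                   run$schedule$concurrent_growth_batches,
                 plant_inventory = run$schedule$plant_inventory,
                 downstream_utilization =
                   run$schedule$downstream_utilization),
            "schedule.json")

  manifest <- structure(list(
    scenario = run$config$scenario,
    package_version = as.character(utils::packageVersion("phytotea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    notes = stage_note,
    files = files,
    checksums = unname(tools::md5sum(files))),
    class = "tea_run_manifest")
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(unclass(manifest), mp, auto_unbox = TRUE,
                       na = "null", pretty = TRUE)
  missing <- manifest$files[!file.exists(manifest$files)]
  if (length(missing)) stop("report files missing after write: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  manifest
}

#' @export
print.tea_run_manifest <- function(x, ...) {
  cat(sprintf("<tea_run_manifest> scenario '%s', %d files\n", x$scenario,
              length(x$files)))
  cat(paste0("  ", x$files, collapse = "\n"), "\n")
  invisible(x)
}
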