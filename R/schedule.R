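#' Facility schedule inputs
#'
#' @param operating_days_per_year Days of operation per year (indoor
#'   facilities run 90 percent of the calendar, 329 days; a field-grown
#'   variant is limited to its growing-season window instead).
#' @param upstream_cycle_days Upstream recipe cycle time (seeding through
#'   incubation), days.
#' @param downstream_cycle_days Downstream recipe cycle time, days.
#' @param batch_duration_days Total batch duration, days.
#' @param requested_batches Integer batch count, or `"max"` to pack as many
#'   batches as the downstream cycle allows.
#' @return Object of class `tea_schedule_inputs`.
#' @export
schedule_inputs <- function(operating_days_per_year = 329,
                            upstream_cycle_days = 41.4,
                            downstream_cycle_days = 0.91,
                            batch_duration_days = upstream_cycle_days +
                              downstream_cycle_days,
                            requested_batches = 91) {
  if (operating_days_per_year <= 0 || operating_days_per_year > 365) {
    stop("operating_days_per_year must lie in (0, 365]", call. = FALSE)
  }
  if (upstream_cycle_days <= 0 || downstream_cycle_days <= 0 ||
      batch_duration_days <= 0) {
    stop("cycle durations must be > 0", call. = FALSE)
  }
  structure(list(operating_days_per_year = operating_days_per_year,
                 upstream_cycle_days = upstream_cycle_days,
                 downstream_cycle_days = downstream_cycle_days,
                 batch_duration_days = batch_duration_days,
                 requested_batches = requested_batches),
            class = "tea_schedule_inputs")
}

#' Build the staggered-batch schedule
#'
#' Batches start at a uniform stagger of
#' `operating_days / batches_per_year`. The number of plant-growth batches
#' in the facility at any time is `ceiling(upstream_cycle / stagger)`, and
#' the standing plant inventory is that concurrency times the plants per
#' batch. The downstream train is the shared resource: its cycle time must
#' fit inside one stagger interval or consecutive harvests would collide.
#'
#' @param inputs A [schedule_inputs()] object.
#' @param plants_per_batch Plants entering each batch.
#' @return Object of class `tea_schedule`: `batches_per_year`,
#'   `stagger_days`, `concurrent_growth_batches`, `plant_inventory`,
#'   `downstream_utilization`.
#' @export
make_schedule <- function(inputs, plants_per_batch) {
  stopifnot(inherits(inputs, "tea_schedule_inputs"))
  batches <- inputs$requested_batches
  if (identical(batches, "max")) {
    batches <- floor(inputs$operating_days_per_year /
                       inputs$downstream_cycle_days)
  }
  if (batches < 1) stop("schedule needs at least one batch", call. = FALSE)
  stagger <- inputs$operating_days_per_year / batches
  if (inputs$downstream_cycle_days > stagger + 1e-9) {
    stop(sprintf(
      paste0("downstream collision: downstream cycle (%.2f d) exceeds the ",
             "stagger between harvests (%.2f d); the downstream train is ",
             "the bottleneck"),
      inputs$downstream_cycle_days, stagger), call. = FALSE)
  }
  concurrent <- ceiling(inputs$upstream_cycle_days / stagger)
  structure(list(batches_per_year = batches,
                 stagger_days = stagger,
                 concurrent_growth_batches = concurrent,
                 plant_inventory = concurrent * plants_per_batch,
                 downstream_utilization = inputs$downstream_cycle_days /
                   stagger,
                 inputs = inputs),
            class = "tea_schedule")
}

#' @export
print.tea_schedule <- function(x, ...) {
  cat(sprintf("<tea_schedule> %d batches/yr, stagger %.2f d\n",
              as.integer(x$batches_per_year), x$stagger_days))
  cat(sprintf("  concurrent growth batches %d, plant inventory %.4g\n",
              as.integer(x$concurrent_growth_batches), x$plant_inventory))
  cat(sprintf("  downstream utilization %.1f%%\n",
              100 * x$downstream_utilization))
  invisible(x)
}

#' Day-by-day occupancy of the plant growth area
#'
#' Brute-force calendar simulation over two steady-state years: batch `b`
#' occupies the growth area from its start day for one upstream cycle.
#' Used as an independent oracle for the closed-form concurrency count, and
#' exportable as a per-day CSV.
#'
#' @param schedule A `tea_schedule` from [make_schedule()].
#' @param years Number of years to simulate (occupancy is measured over the
#'   final year, after start-up transients).
#' @return A data.frame with columns `day` and `growth_batches_occupying`.
#' @export
simulate_occupancy <- function(schedule, years = 2) {
  stopifnot(inherits(schedule, "tea_schedule"))
  inp <- schedule$inputs
  starts <- as.vector(outer(
    (seq_len(schedule$batches_per_year) - 1) * schedule$stagger_days,
    (seq_len(years) - 1) * inp$operating_days_per_year, "+"))
  ends <- starts + inp$upstream_cycle_days
  last_year <- seq(floor((years - 1) * inp$operating_days_per_year) + 1,
                   floor(years * inp$operating_days_per_year))
  occ <- vapply(last_year, function(d) {
    sum(starts <= d - 1 & ends > d - 1)
  }, numeric(1))
  data.frame(day = last_year, growth_batches_occupying = occ)
}
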