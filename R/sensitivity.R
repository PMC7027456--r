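# Facility rescaling rules shared by the scans. Every ledger and equipment
# item carries a scale_with tag naming the facility quantity it follows:
#   biomass -> fresh weight processed (plants, substrate, nutrients, LED)
#   volume  -> extract volume through clarification (tracks FW at fixed
#              extraction ratio)
#   product -> AMP quantity handled (chromatography, diafiltration, dryer)
#   fixed   -> capacity-independent base loads (staffed labor, QC)
scale_factors <- function(scale_with, fw_ratio, demand_ratio) {
  vapply(scale_with, function(s) switch(s,
    biomass = fw_ratio,
    volume = fw_ratio,
    product = demand_ratio,
    fixed = 1), numeric(1), USE.NAMES = FALSE)
}

scale_ledger <- function(ledger, fw_ratio, demand_ratio) {
  f <- scale_factors(ledger$scale_with, fw_ratio, demand_ratio)
  has_qty <- !is.na(ledger$annual_quantity)
  ledger$annual_quantity[has_qty] <- ledger$annual_quantity[has_qty] *
    f[has_qty]
  ledger$annual_cost <- ledger$annual_cost * f
  ledger
}

scale_equipment <- function(equipment, fw_ratio, demand_ratio) {
  f <- scale_factors(equipment$scale_with, fw_ratio, demand_ratio)
  equipment$actual_size <- equipment$actual_size * f
  equipment
}

#' Purchase-price sensitivity of COGS
#'
#' Perturbs one ledger item's price by the given fractions and recomputes
#' COGS from the full ledger. Because COGS is a linear functional of the
#' ledger, the response is exactly
#' `delta x (item annual cost / AOC) x 100` percent.
#'
#' @param config A [scenario_config()].
#' @param item_name Ledger item to perturb (error lists the valid names).
#' @param deltas Signed price perturbations as fractions (e.g. `c(-0.3,
#'   0.3)` for +/-30 percent).
#' @return Data.frame with columns `delta`, `cogs_per_g` and
#'   `cogs_change_pct`.
#' @export
price_sensitivity <- function(config, item_name,
                              deltas = c(-0.3, -0.2, -0.1, 0.1, 0.2, 0.3)) {
  stopifnot(inherits(config, "tea_config"))
  led <- config$ledger
  if (!item_name %in% led$name) {
    stop("unknown ledger item '", item_name, "'; ledger contains: ",
         paste(led$name, collapse = ", "), call. = FALSE)
  }
  base_cogs <- cogs(opex(led)$aoc, config$demand_kg)$cogs_per_g
  res <- lapply(deltas, function(d) {
    led2 <- led
    i <- led2$name == item_name
    led2$annual_cost[i] <- led2$annual_cost[i] * (1 + d)
    led2$unit_price[i] <- led2$unit_price[i] * (1 + d)
    cg <- cogs(opex(led2)$aoc, config$demand_kg)$cogs_per_g
    data.frame(delta = d, cogs_per_g = cg,
               cogs_change_pct = 100 * (cg - base_cogs) / base_cogs)
  })
  do.call(rbind, res)
}

#' Expression-level scan
#'
#' Re-sizes the facility over a grid of expression levels at fixed annual
#' demand and fixed downstream recovery (recovery is deliberately held
#' constant across expression levels). Biomass- and volume-driven costs
#' scale with the fresh weight requirement (proportional to 1/E);
#' product-quantity-driven and fixed costs are unchanged. Equipment is
#' resized continuously through its capacity exponent.
#'
#' @param config A [scenario_config()].
#' @param expression_levels Grid of expression levels, g AMP/kg FW,
#'   strictly increasing.
#' @return A `tea_scan` data.frame: one row per grid point with COGS,
#'   CAPEX, AOC and their upstream/downstream splits.
#' @export
expression_scan <- function(config,
                            expression_levels = seq(0.5, 5, by = 0.5)) {
  stopifnot(inherits(config, "tea_config"))
  if (any(expression_levels <= 0)) {
    stop("expression levels must be positive", call. = FALSE)
  }
  if (is.unsorted(expression_levels, strictly = TRUE)) {
    stop("expression grid must be strictly increasing", call. = FALSE)
  }
  e0 <- config$host$expression_g_per_kg
  base_fw <- size_batches(config$demand_kg, config$overall_recovery, e0,
                          config$batches)$fw_per_batch_kg
  rows <- lapply(expression_levels, function(e) {
    fw_ratio <- e0 / e
    rep <- cost_report(scale_equipment(config$equipment, fw_ratio, 1),
                       scale_ledger(config$ledger, fw_ratio, 1),
                       config$demand_kg)
    data.frame(expression_g_per_kg = e,
               fw_per_batch_kg = base_fw * fw_ratio,
               cogs_per_g = rep$cogs_per_g,
               cogs_upstream_per_g = rep$cogs_upstream_per_g,
               cogs_downstream_per_g = rep$cogs_downstream_per_g,
               aoc = rep$aoc,
               capex_total = rep$capex_total,
               capex_upstream = rep$capex_by_section[["upstream"]],
               capex_downstream = rep$capex_by_section[["downstream"]])
  })
  structure(do.call(rbind, rows), class = c("tea_scan", "data.frame"),
            parameter = "expression_g_per_kg")
}

#' Annual-production scan
#'
#' Re-sizes the facility over a grid of annual production levels at fixed
#' expression level. Upstream (biomass/volume) costs scale linearly with
#' demand — the near-linear scalability of the plant platform — while fixed
#' downstream base loads (staffed labor, QC, dryer base load) do not, so
#' the downstream share of COGS falls as production grows.
#'
#' @param config A [scenario_config()].
#' @param demands Grid of annual production levels, kg AMP/yr, strictly
#'   increasing.
#' @return A `tea_scan` data.frame with COGS splits and the downstream
#'   share per grid point.
#' @export
production_scan <- function(config, demands = seq(100, 1000, by = 100)) {
  stopifnot(inherits(config, "tea_config"))
  if (any(demands <= 0)) stop("demands must be positive", call. = FALSE)
  if (is.unsorted(demands, strictly = TRUE)) {
    stop("demand grid must be strictly increasing", call. = FALSE)
  }
  d0 <- config$demand_kg
  rows <- lapply(demands, function(d) {
    ratio <- d / d0
    rep <- cost_report(scale_equipment(config$equipment, ratio, ratio),
                       scale_ledger(config$ledger, ratio, ratio), d)
    data.frame(annual_demand_kg = d,
               cogs_per_g = rep$cogs_per_g,
               cogs_upstream_per_g = rep$cogs_upstream_per_g,
               cogs_downstream_per_g = rep$cogs_downstream_per_g,
               downstream_share_pct = 100 * rep$cogs_downstream_per_g /
                 rep$cogs_per_g,
               aoc = rep$aoc,
               capex_total = rep$capex_total)
  })
  structure(do.call(rbind, rows), class = c("tea_scan", "data.frame"),
            parameter = "annual_demand_kg")
}

#' Cost of use at a food-processing juncture
#'
#' Converts a production cost into a treatment cost at the application
#' rates expected for antimicrobial-protein food safety interventions:
#' 2–10 mg AMP per kg of meat product, or 2–10 ppm (mg/L) in animal or
#' carcass wash water. For reference, standard food sanitizing treatments
#' run $0.01–0.10 per kg of food.
#'
#' @param cogs_per_g Production cost, $/g AMP.
#' @param juncture `"meat_product"` ($ per kg food), `"animal_wash"` or
#'   `"carcass_spray"` ($ per L wash water).
#' @param rate_range Application rate range `c(low, high)` in mg/kg (meat)
#'   or mg/L (washes).
#' @return Object of class `tea_cost_of_use` with the cost band and units.
#' @export
cost_of_use <- function(cogs_per_g,
                        juncture = c("meat_product", "animal_wash",
                                     "carcass_spray"),
                        rate_range = c(2, 10)) {
  juncture <- match.arg(juncture)
  if (any(rate_range < 0) || rate_range[2] < rate_range[1]) {
    stop("rate_range must be ordered and non-negative", call. = FALSE)
  }
  cost <- rate_range * cogs_per_g / 1000  # mg x $/g -> $
  unit <- if (juncture == "meat_product") "$ per kg food" else
    "$ per L wash water"
  structure(list(juncture = juncture,
                 rate_range = rate_range,
                 rate_unit = if (juncture == "meat_product") "mg AMP/kg food"
                   else "mg AMP/L (ppm)",
                 cost_low = cost[1], cost_high = cost[2],
                 cost_unit = unit,
                 standard_treatment_band = c(low = 0.01, high = 0.10)),
            class = "tea_cost_of_use")
}

#' @export
print.tea_cost_of_use <- function(x, ...) {
  cat(sprintf("<tea_cost_of_use> %s at %g-%g %s\n", x$juncture,
              x$rate_range[1], x$rate_range[2], x$rate_unit))
  cat(sprintf("  cost %.4f-%.4f %s (standard treatments: %.2f-%.2f $/kg food)\n",
              x$cost_low, x$cost_high, x$cost_unit,
              x$standard_treatment_band[["low"]],
              x$standard_treatment_band[["high"]]))
  invisible(x)
}
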