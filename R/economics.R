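#' Equipment list item
#'
#' Purchased-equipment entry for CAPEX estimation. The installed cost
#' follows the standard capacity-exponent rule,
#' `reference_cost * (actual_size / reference_size)^exponent * multiplier`,
#' with the six-tenths exponent as the default for process equipment.
#'
#' @param name Equipment name.
#' @param section `"upstream"` or `"downstream"`.
#' @param reference_cost Purchase cost at the reference size, $.
#' @param reference_size,actual_size Capacity in any consistent unit.
#' @param scaling_exponent Capacity exponent in (0, 1].
#' @param installation_multiplier Installed-cost (Lang-type) multiplier.
#' @param scale_with `"biomass"`, `"volume"`, `"product"` or `"fixed"`:
#'   which facility quantity resizes this item in scans.
#' @return One-row data.frame.
#' @export
equipment_item <- function(name, section, reference_cost,
                           reference_size = 1, actual_size = reference_size,
                           scaling_exponent = 0.6,
                           installation_multiplier = 1,
                           scale_with = "volume") {
  if (reference_cost <= 0) stop("reference_cost must be > 0", call. = FALSE)
  if (reference_size <= 0 || actual_size <= 0) {
    stop("equipment sizes must be > 0", call. = FALSE)
  }
  if (scaling_exponent <= 0 || scaling_exponent > 1) {
    stop("scaling_exponent must lie in (0, 1]", call. = FALSE)
  }
  section <- match.arg(section, c("upstream", "downstream"))
  scale_with <- match.arg(scale_with,
                          c("biomass", "volume", "product", "fixed"))
  data.frame(name = name, section = section,
             reference_cost = reference_cost,
             reference_size = reference_size, actual_size = actual_size,
             scaling_exponent = scaling_exponent,
             installation_multiplier = installation_multiplier,
             scale_with = scale_with, stringsAsFactors = FALSE)
}

#' CAPEX rollup from an equipment list
#'
#' @param equipment A data.frame of [equipment_item()] rows.
#' @return Object of class `tea_capex`: per-item installed costs, section
#'   sums and total.
#' @export
capex <- function(equipment) {
  if (!NROW(equipment)) stop("equipment list must be non-empty", call. = FALSE)
  if (any(equipment$actual_size <= 0) || any(equipment$reference_size <= 0)) {
    stop("equipment sizes must be > 0", call. = FALSE)
  }
  cost <- equipment$reference_cost *
    (equipment$actual_size / equipment$reference_size)^
      equipment$scaling_exponent *
    equipment$installation_multiplier
  by_section <- tapply(cost, factor(equipment$section,
                                    c("upstream", "downstream")), sum,
                       default = 0)
  structure(list(items = cbind(equipment, installed_cost = cost),
                 by_section = c(upstream = unname(by_section[["upstream"]]),
                                downstream = unname(by_section[["downstream"]])),
                 total = sum(cost)),
            class = "tea_capex")
}

#' Operating-cost ledger item
#'
#' Either give `annual_quantity` and `unit_price` (annual cost is their
#' product) or a pinned `annual_cost` directly.
#'
#' @param name Item name.
#' @param section `"upstream"` or `"downstream"`.
#' @param category One of `raw_material`, `consumable`, `labor`, `utility`,
#'   `waste`, `qc_qa`, `other`.
#' @param annual_quantity,unit_price Quantity per year and $ per unit.
#' @param annual_cost Annual cost, $ (computed when quantity and price are
#'   given).
#' @param scale_with `"biomass"`, `"volume"`, `"product"` or `"fixed"`:
#'   which facility quantity this cost follows when the facility is resized
#'   (biomass-driven consumables track FW, volume-driven items track the
#'   extract volume, product-driven items track the AMP output, fixed items
#'   are capacity-independent base loads such as staffed labor).
#' @return One-row data.frame.
#' @export
cost_item <- function(name, section, category,
                      annual_quantity = NA_real_, unit_price = NA_real_,
                      annual_cost = NULL, scale_with = "fixed") {
  section <- match.arg(section, c("upstream", "downstream"))
  category <- match.arg(category, c("raw_material", "consumable", "labor",
                                    "utility", "waste", "qc_qa", "other"))
  scale_with <- match.arg(scale_with,
                          c("biomass", "volume", "product", "fixed"))
  if (is.null(annual_cost)) {
    if (is.na(annual_quantity) || is.na(unit_price)) {
      stop("give either annual_cost or both annual_quantity and unit_price",
           call. = FALSE)
    }
    annual_cost <- annual_quantity * unit_price
  }
  if (annual_cost < 0 ||
      (!is.na(annual_quantity) && annual_quantity < 0) ||
      (!is.na(unit_price) && unit_price < 0)) {
    stop("cost item quantities, prices and costs must be >= 0", call. = FALSE)
  }
  data.frame(name = name, section = section, category = category,
             annual_quantity = annual_quantity, unit_price = unit_price,
             annual_cost = annual_cost, scale_with = scale_with,
             stringsAsFactors = FALSE)
}

#' OPEX rollup from a cost ledger
#'
#' @param ledger Data.frame of [cost_item()] rows.
#' @return Object of class `tea_opex`: `aoc` (total annual operating cost,
#'   $/yr), `by_section`, `by_category` and the item table sorted by
#'   descending cost (deterministic report order).
#' @export
opex <- function(ledger) {
  if (!NROW(ledger)) stop("ledger must be non-empty", call. = FALSE)
  qp <- !is.na(ledger$annual_quantity) & !is.na(ledger$unit_price)
  bad <- qp & abs(ledger$annual_cost -
                    ledger$annual_quantity * ledger$unit_price) >
    1e-6 * pmax(1, ledger$annual_cost)
  if (any(bad)) {
    stop("ledger arithmetic violation (cost != quantity x price): ",
         paste(ledger$name[bad], collapse = ", "), call. = FALSE)
  }
  by_section <- tapply(ledger$annual_cost,
                       factor(ledger$section, c("upstream", "downstream")),
                       sum, default = 0)
  cats <- c("raw_material", "consumable", "labor", "utility", "waste",
            "qc_qa", "other")
  by_category <- tapply(ledger$annual_cost, factor(ledger$category, cats),
                        sum, default = 0)
  by_category[is.na(by_category)] <- 0
  ord <- order(-ledger$annual_cost, ledger$name)
  structure(list(aoc = sum(ledger$annual_cost),
                 by_section = c(upstream = unname(by_section[["upstream"]]),
                                downstream = unname(by_section[["downstream"]])),
                 by_category = stats::setNames(as.vector(by_category), cats),
                 items = ledger[ord, , drop = FALSE]),
            class = "tea_opex")
}

#' Cost of goods sold per gram
#'
#' COGS is the annual operating cost over the annual product mass; capital
#' is reported separately and no depreciation charge is folded in, so the
#' identity `COGS = AOC / demand` holds exactly.
#'
#' @param aoc Annual operating cost, $/yr.
#' @param annual_demand_kg Annual formulated AMP output, kg/yr.
#' @param section_split Optional named vector `c(upstream=, downstream=)` of
#'   annual cost by section, $/yr.
#' @return List with `cogs_per_g` and, when the split is given,
#'   `cogs_upstream_per_g` / `cogs_downstream_per_g`.
#' @export
cogs <- function(aoc, annual_demand_kg, section_split = NULL) {
  if (annual_demand_kg <= 0) stop("annual demand must be > 0", call. = FALSE)
  grams <- annual_demand_kg * 1000
  out <- list(cogs_per_g = aoc / grams)
  if (!is.null(section_split)) {
    out$cogs_upstream_per_g <- section_split[["upstream"]] / grams
    out$cogs_downstream_per_g <- section_split[["downstream"]] / grams
  }
  out
}

#' Optional straight-line depreciation report line
#'
#' Provided for reporting only; never folded into COGS.
#'
#' @param capex_total Total CAPEX, $.
#' @param lifetime_years Depreciation period, years.
#' @param salvage_fraction Salvage value fraction of CAPEX.
#' @return Annual depreciation, $/yr.
#' @export
straight_line_depreciation <- function(capex_total, lifetime_years = 15,
                                       salvage_fraction = 0.05) {
  capex_total * (1 - salvage_fraction) / lifetime_years
}

#' Full cost report: CAPEX, OPEX, COGS and shares
#'
#' @param equipment Equipment data.frame.
#' @param ledger Cost ledger data.frame.
#' @param annual_demand_kg Annual formulated AMP output, kg/yr.
#' @return Object of class `tea_cost_report`.
#' @export
cost_report <- function(equipment, ledger, annual_demand_kg) {
  cap <- capex(equipment)
  op <- opex(ledger)
  cg <- cogs(op$aoc, annual_demand_kg, op$by_section)
  shares <- list(
    capex_section_pct = 100 * cap$by_section / cap$total,
    opex_section_pct = 100 * op$by_section / op$aoc,
    category_pct = 100 * op$by_category / op$aoc,
    item_pct = stats::setNames(100 * op$items$annual_cost / op$aoc,
                               op$items$name))
  structure(list(capex = cap, opex = op,
                 capex_by_section = cap$by_section,
                 capex_total = cap$total,
                 opex_by_section = op$by_section,
                 aoc = op$aoc,
                 annual_demand_kg = annual_demand_kg,
                 cogs_per_g = cg$cogs_per_g,
                 cogs_upstream_per_g = cg$cogs_upstream_per_g,
                 cogs_downstream_per_g = cg$cogs_downstream_per_g,
                 shares = shares),
            class = "tea_cost_report")
}

#' @export
print.tea_cost_report <- function(x, ...) {
  cat("<tea_cost_report>\n")
  cat(sprintf("  CAPEX  $ million      Upstream %6.3g  Downstream %6.3g  Total %6.3g\n",
              x$capex_by_section[["upstream"]] / 1e6,
              x$capex_by_section[["downstream"]] / 1e6, x$capex_total / 1e6))
  cat(sprintf("  OPEX   $ million/year Upstream %6.3g  Downstream %6.3g  Total %6.3g\n",
              x$opex_by_section[["upstream"]] / 1e6,
              x$opex_by_section[["downstream"]] / 1e6, x$aoc / 1e6))
  cat(sprintf("  COGS   $/g AMP        Upstream %6.3g  Downstream %6.3g  Total %6.3g\n",
              x$cogs_upstream_per_g, x$cogs_downstream_per_g, x$cogs_per_g))
  invisible(x)
}

#' Table 2-style scenario summary rows
#'
#' @param report A `tea_cost_report`.
#' @return Data.frame with parameter / unit / section / value columns.
#' @export
summary_table <- function(report) {
  stopifnot(inherits(report, "tea_cost_report"))
  data.frame(
    parameter = rep(c("CAPEX", "OPEX", "COGS"), each = 3),
    unit = rep(c("$ million", "$ million/year", "$/g AMP"), each = 3),
    section = rep(c("Upstream", "Downstream", "Total"), 3),
    value = c(report$capex_by_section[["upstream"]] / 1e6,
              report$capex_by_section[["downstream"]] / 1e6,
              report$capex_total / 1e6,
              report$opex_by_section[["upstream"]] / 1e6,
              report$opex_by_section[["downstream"]] / 1e6,
              report$aoc / 1e6,
              report$cogs_upstream_per_g,
              report$cogs_downstream_per_g,
              report$cogs_per_g),
    row.names = NULL)
}
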