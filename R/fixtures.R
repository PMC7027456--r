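# Scenario fixtures: reconstructed facility configurations calibrated to the
# reference facility's printed aggregates. Calibration order is fixed:
# (1) the mass balance is pinned by the printed per-batch stream table,
# (2) the schedule by the printed operating calendar and batch count,
# (3) the operating-cost ledger by the printed section/operation shares with
#     residual allocation to labor/utility/resin/membrane items,
# (4) the equipment list by the printed CAPEX section totals.
# Later stages never alter earlier pins.

#' Reference unit prices
#'
#' Unit prices used by the quantity-driven ledger items. The substrate price
#' is set inside the printed "1.3 cents per plant" rounding so that the
#' substrate share of annual operating cost equals the reported 41.2
#' percent.
#'
#' @return Named list of prices.
#' @export
reference_prices <- function() {
  list(substrate_per_plant = 0.01277,   # $ per plant, "1.3 cents" rounding
       seed_per_g = 9.50,               # $ per g of seed stock
       seeds_per_g = 9500,              # seeds per g
       nutrient_per_L = 0.035,          # $ per L nutrient solution
       nutrient_waste_per_L = 0.010,    # $ per L biowaste disposal
       ethanol_solution_per_L = 0.81)   # $ per L of 4% (v/v) induction spray
}

host_fixture <- function(variant) {
  p <- variant_params(variant)
  switch(variant,
    base = host_params("Nicotiana benthamiana",
                       # back-derived: 9,520 kg FW / 1.22e6 plants per batch
                       fw_per_plant_g = 9520 / 1.22e6 * 1000,
                       has_alkaloid = TRUE),
    spinach = host_params("Spinacia oleracea",
                          # back-derived: batch FW / 1.08e6 plants per batch
                          fw_per_plant_g = p$fw_per_batch_kg / 1.08e6 * 1000,
                          has_alkaloid = FALSE),
    tobacco = host_params("Nicotiana tabacum (field)",
                          # back-derived: batch FW / 13,900 plants per batch
                          fw_per_plant_g = p$fw_per_batch_kg / 13900 * 1000,
                          growth_days = 82.4,
                          has_alkaloid = TRUE,
                          nutrient_demand_L_per_kg = 0,
                          nutrient_waste_L_per_kg = 0,
                          field_grown = TRUE))
}

schedule_fixture <- function(variant) {
  switch(variant,
    base = list(operating_days_per_year = 329, upstream_cycle_days = 41.4,
                downstream_cycle_days = 0.91),
    spinach = list(operating_days_per_year = 329, upstream_cycle_days = 41.4,
                   downstream_cycle_days = 0.67),
    # field window: late March to late October, ~214 days
    tobacco = list(operating_days_per_year = 214, upstream_cycle_days = 88.4,
                   downstream_cycle_days = 1.08))
}

# annual operating cost ledgers, calibrated to the printed section totals.
# Quantity-driven items come straight from the upstream plan at the
# reference unit prices; pinned shares (seeding operation 79% of upstream
# OPEX, chromatography 38% and UF/DF 35% of downstream OPEX, downstream
# labor 18.5% of AOC, elution buffer 1.37% of AOC) are imposed exactly, and
# the residual in each group is absorbed by its labor / utility / resin /
# membrane item.
ledger_fixture <- function(variant, plan, chain) {
  pr <- reference_prices()
  plants_yr <- plan$plants_per_batch * plan$batches_per_year
  fw_yr <- plan$annual_fw_kg
  seed <- seed_and_tray_demand(plan, pr$seeds_per_g, pr$seed_per_g)
  eth <- induction_demand(plan)

  if (variant == "base") {
    up_target <- 2.01e6
    ds_target <- 1.43e6
    aoc_target <- up_target + ds_target
    seeding_target <- 0.79 * up_target       # seeding op share of upstream
    chrom_target <- 0.38 * ds_target         # chromatography op share
    ufdf_target <- 0.35 * ds_target          # UF/DF op share
    ds_labor_target <- 0.185 * aoc_target    # downstream labor-dependent
    elution_target <- 0.0137 * aoc_target    # elution buffer share

    substrate <- cost_item("soilless plant substrate", "upstream",
                           "consumable", plants_yr, pr$substrate_per_plant,
                           scale_with = "biomass")
    seeds <- cost_item("transgenic seed stock", "upstream", "raw_material",
                       seed$seed_g_per_year, pr$seed_per_g,
                       scale_with = "biomass")
    supplies <- cost_item("seeding supplies & tray wash", "upstream",
                          "consumable", annual_cost = 19100,
                          scale_with = "biomass")
    seeding_labor <- cost_item("seeding labor", "upstream", "labor",
                               annual_cost = seeding_target -
                                 substrate$annual_cost - seeds$annual_cost -
                                 supplies$annual_cost,
                               scale_with = "biomass")
    nutrients <- cost_item("hydroponic nutrient solution", "upstream",
                           "raw_material",
                           plan$nutrient_demand_per_batch_L *
                             plan$batches_per_year, pr$nutrient_per_L,
                           scale_with = "biomass")
    nut_waste <- cost_item("spent nutrient biowaste disposal", "upstream",
                           "waste",
                           plan$nutrient_waste_per_batch_L *
                             plan$batches_per_year,
                           pr$nutrient_waste_per_L, scale_with = "biomass")
    ethanol <- cost_item("induction ethanol solution (4% v/v)", "upstream",
                         "raw_material", eth$per_year_L,
                         pr$ethanol_solution_per_L, scale_with = "biomass")
    qc_up <- cost_item("upstream QC/QA (GACP)", "upstream", "qc_qa",
                       annual_cost = 40000, scale_with = "fixed")
    util_up <- cost_item("LED lighting & HVAC utilities", "upstream",
                         "utility", annual_cost = 200000,
                         scale_with = "biomass")
    growth_labor <- cost_item("plant growth & induction labor", "upstream",
                              "labor",
                              annual_cost = up_target - seeding_target -
                                nutrients$annual_cost -
                                nut_waste$annual_cost -
                                ethanol$annual_cost - qc_up$annual_cost -
                                util_up$annual_cost,
                              scale_with = "biomass")

    # elution buffer quantity from the chain itself (eluate mass per batch)
    cex <- chain[[3]]
    eluate_per_batch <- cex$added_inputs[[1]]$ratio *
      0.0141 * 476                           # kg eluate per kg AMP x AMP fed
    elution_qty <- eluate_per_batch * plan$batches_per_year
    elution <- cost_item("chromatography elution buffer", "downstream",
                         "raw_material", elution_qty,
                         elution_target / elution_qty,
                         scale_with = "product")
    chrom_util <- cost_item("chromatography utilities", "downstream",
                            "utility", annual_cost = 35000,
                            scale_with = "product")
    chrom_labor <- cost_item("chromatography labor", "downstream", "labor",
                             annual_cost = 185000, scale_with = "fixed")
    resin <- cost_item("CEX resin", "downstream", "consumable",
                       annual_cost = chrom_target - elution$annual_cost -
                         chrom_util$annual_cost - chrom_labor$annual_cost,
                       scale_with = "product")
    pbs <- cost_item("PBS diafiltration buffer", "downstream",
                     "raw_material", annual_cost = 25000,
                     scale_with = "product")
    ufdf_labor <- cost_item("UF/DF labor", "downstream", "labor",
                            annual_cost = 195000, scale_with = "fixed")
    membranes <- cost_item("TFF membranes (MF/UF/DF)", "downstream",
                           "consumable",
                           annual_cost = ufdf_target - pbs$annual_cost -
                             ufdf_labor$annual_cost,
                           scale_with = "volume")
    harv_labor <- cost_item("harvest & clarification labor", "downstream",
                            "labor",
                            annual_cost = ds_labor_target -
                              chrom_labor$annual_cost -
                              ufdf_labor$annual_cost,
                            scale_with = "fixed")
    cip <- cost_item("CIP/SIP chemicals", "downstream", "raw_material",
                     annual_cost = 40000, scale_with = "volume")
    spray_util <- cost_item("spray dryer utilities", "downstream", "utility",
                            annual_cost = 30000, scale_with = "fixed")
    qc_ds <- cost_item("downstream QC/QA (cGMP)", "downstream", "qc_qa",
                       annual_cost = 40000, scale_with = "fixed")
    ds_waste <- cost_item("downstream waste disposal", "downstream", "waste",
                          annual_cost = ds_target - chrom_target -
                            ufdf_target - harv_labor$annual_cost -
                            cip$annual_cost - spray_util$annual_cost -
                            qc_ds$annual_cost,
                          scale_with = "volume")

    ledger <- rbind(substrate, seeds, supplies, seeding_labor, nutrients,
                    nut_waste, ethanol, qc_up, util_up, growth_labor,
                    elution, chrom_util, chrom_labor, resin, pbs, ufdf_labor,
                    membranes, harv_labor, cip, spray_util, qc_ds, ds_waste)
    ledger$operation <- c("seeding", "seeding", "seeding", "seeding",
                          "growth", "growth", "induction", "qc", "growth",
                          "growth", "chromatography", "chromatography",
                          "chromatography", "chromatography", "ufdf",
                          "ufdf", "ufdf", "harvest_clarification", "cip",
                          "spray_dry", "qc", "waste")
    return(ledger)
  }

  if (variant == "spinach") {
    up_target <- 1.76e6   # COGS row: $3.52/g upstream x 500,000 g
    ds_target <- 0.70e6   # COGS row: $1.40/g downstream
    substrate <- cost_item("soilless plant substrate", "upstream",
                           "consumable", plants_yr, pr$substrate_per_plant,
                           scale_with = "biomass")
    seeds <- cost_item("transgenic seed stock", "upstream", "raw_material",
                       seed$seed_g_per_year, pr$seed_per_g,
                       scale_with = "biomass")
    nutrients <- cost_item("hydroponic nutrient solution", "upstream",
                           "raw_material",
                           plan$nutrient_demand_per_batch_L *
                             plan$batches_per_year, pr$nutrient_per_L,
                           scale_with = "biomass")
    nut_waste <- cost_item("spent nutrient biowaste disposal", "upstream",
                           "waste",
                           plan$nutrient_waste_per_batch_L *
                             plan$batches_per_year,
                           pr$nutrient_waste_per_L, scale_with = "biomass")
    ethanol <- cost_item("induction ethanol solution (4% v/v)", "upstream",
                         "raw_material", eth$per_year_L,
                         pr$ethanol_solution_per_L, scale_with = "biomass")
    qc_up <- cost_item("upstream QC/QA (GACP)", "upstream", "qc_qa",
                       annual_cost = 40000, scale_with = "fixed")
    util_up <- cost_item("LED lighting & HVAC utilities", "upstream",
                         "utility", annual_cost = 190000,
                         scale_with = "biomass")
    up_labor <- cost_item("upstream labor (seeding & growth)", "upstream",
                          "labor",
                          annual_cost = up_target - substrate$annual_cost -
                            seeds$annual_cost - nutrients$annual_cost -
                            nut_waste$annual_cost - ethanol$annual_cost -
                            qc_up$annual_cost - util_up$annual_cost,
                          scale_with = "biomass")
    # 37% reduction in downstream labor vs the base case after removing CEX
    ds_labor <- cost_item("downstream labor", "downstream", "labor",
                          annual_cost = 401000, scale_with = "fixed")
    pbs <- cost_item("PBS diafiltration buffer", "downstream",
                     "raw_material", annual_cost = 20000,
                     scale_with = "product")
    cip <- cost_item("CIP/SIP chemicals", "downstream", "raw_material",
                     annual_cost = 35000, scale_with = "volume")
    spray_util <- cost_item("spray dryer utilities", "downstream", "utility",
                            annual_cost = 28000, scale_with = "fixed")
    qc_ds <- cost_item("downstream QC/QA (cGMP)", "downstream", "qc_qa",
                       annual_cost = 38000, scale_with = "fixed")
    ds_waste <- cost_item("downstream waste disposal", "downstream", "waste",
                          annual_cost = 15000, scale_with = "volume")
    membranes <- cost_item("TFF membranes (MF/UF/DF)", "downstream",
                           "consumable",
                           annual_cost = ds_target - ds_labor$annual_cost -
                             pbs$annual_cost - cip$annual_cost -
                             spray_util$annual_cost - qc_ds$annual_cost -
                             ds_waste$annual_cost,
                           scale_with = "volume")
    ledger <- rbind(substrate, seeds, nutrients, nut_waste, ethanol, qc_up,
                    util_up, up_labor, ds_labor, pbs, cip, spray_util,
                    qc_ds, ds_waste, membranes)
    ledger$operation <- c("seeding", "seeding", "growth", "growth",
                          "induction", "qc", "growth", "growth", "labor",
                          "ufdf", "cip", "spray_dry", "qc", "waste", "ufdf")
    return(ledger)
  }

  # tobacco: outdoor field growth, COGS row 0.555 + 2.45 $/g
  up_target <- 0.555 * 5e5
  ds_target <- 2.45 * 5e5
  seeds <- cost_item("transgenic seed stock (direct field seeding)",
                     "upstream", "raw_material", seed$seed_g_per_year,
                     pr$seed_per_g, scale_with = "biomass")
  field_ops <- cost_item("field operations (fuel, fertilizer, machinery)",
                         "upstream", "other", annual_cost = 120000,
                         scale_with = "biomass")
  qc_up <- cost_item("field QC & transgenic monitoring", "upstream",
                     "qc_qa", annual_cost = 30000, scale_with = "fixed")
  field_labor <- cost_item("dedicated field crew", "upstream", "labor",
                           annual_cost = up_target - seeds$annual_cost -
                             field_ops$annual_cost - qc_up$annual_cost,
                           scale_with = "fixed")
  elution <- cost_item("chromatography elution buffer", "downstream",
                       "raw_material", annual_cost = 40000,
                       scale_with = "product")
  resin <- cost_item("CEX resin", "downstream", "consumable",
                     annual_cost = 230000, scale_with = "product")
  chrom_util <- cost_item("chromatography utilities", "downstream",
                          "utility", annual_cost = 30000,
                          scale_with = "product")
  membranes <- cost_item("TFF membranes (MF/UF/DF)", "downstream",
                         "consumable", annual_cost = 240000,
                         scale_with = "volume")
  pbs <- cost_item("PBS diafiltration buffer", "downstream", "raw_material",
                   annual_cost = 22000, scale_with = "product")
  cip <- cost_item("CIP/SIP chemicals", "downstream", "raw_material",
                   annual_cost = 40000, scale_with = "volume")
  spray_util <- cost_item("spray dryer utilities", "downstream", "utility",
                          annual_cost = 32000, scale_with = "fixed")
  qc_ds <- cost_item("downstream QC/QA (cGMP)", "downstream", "qc_qa",
                     annual_cost = 40000, scale_with = "fixed")
  ds_waste <- cost_item("downstream waste disposal", "downstream", "waste",
                        annual_cost = 18000, scale_with = "volume")
  ds_labor <- cost_item("downstream labor", "downstream", "labor",
                        annual_cost = ds_target - elution$annual_cost -
                          resin$annual_cost - chrom_util$annual_cost -
                          membranes$annual_cost - pbs$annual_cost -
                          cip$annual_cost - spray_util$annual_cost -
                          qc_ds$annual_cost - ds_waste$annual_cost,
                        scale_with = "fixed")
  ledger <- rbind(seeds, field_ops, qc_up, field_labor, elution, resin,
                  chrom_util, membranes, pbs, cip, spray_util, qc_ds,
                  ds_waste, ds_labor)
  ledger$operation <- c("seeding", "growth", "qc", "growth",
                        "chromatography", "chromatography",
                        "chromatography", "ufdf", "ufdf", "cip",
                        "spray_dry", "qc", "waste", "labor")
  ledger
}

equipment_fixture <- function(variant) {
  up <- function(name, ref) {
    equipment_item(name, "upstream", ref, scaling_exponent = 0.9,
                   installation_multiplier = 3.0, scale_with = "biomass")
  }
  ds <- function(name, ref, scale_with = "volume") {
    equipment_item(name, "downstream", ref, scaling_exponent = 0.6,
                   installation_multiplier = 3.0, scale_with = scale_with)
  }
  if (variant == "base") {
    return(rbind(
      up("vertical cultivation racks & LED", 3.2e6),
      up("hydroponic nutrient system", 1.0e6),
      up("induction & spray system", 0.5e6),
      up("automated harvesters & conveyors", 1.0e6),
      up("seeding line", 2.0e6 / 3),
      ds("disintegrator & screw press", 0.27e6),
      ds("microfiltration skid", 2.4e6),
      ds("UF/DF skid", 7.99e6 / 3),
      ds("CEX column & skid", 2.0e6, "product"),
      ds("spray dryer", 1.8e6, "product"),
      ds("tanks & CIP/SIP", 1.2e6)))
  }
  if (variant == "spinach") {
    return(rbind(
      up("vertical cultivation racks & LED", 3.2e6),
      up("hydroponic nutrient system", 1.0e6),
      up("induction & spray system", 0.5e6),
      up("automated harvesters & conveyors", 1.0e6),
      up("seeding line", 2.0e6 / 3),
      ds("disintegrator & screw press", 0.3e6),
      ds("microfiltration skid", 2.5e6),
      ds("UF/DF skid", 9.4e6 / 3),
      ds("spray dryer", 1.9e6, "product"),
      ds("tanks & CIP/SIP", 1.3e6)))
  }
  rbind(
    up("field machinery (planters, harvesters, tractors)", 1.3e6 / 3),
    ds("disintegrator & screw press", 0.8e6 / 3),
    ds("microfiltration skid", 2.1e6),
    ds("UF/DF skid", 2.3e6),
    ds("CEX column & skid", 5.2e6 / 3, "product"),
    ds("spray dryer", 4.4e6 / 3, "product"),
    ds("tanks & CIP/SIP", 2.6e6 / 3))
}

#' Assemble a complete scenario configuration
#'
#' The full facility description for one scenario: host parameters,
#' downstream chain, schedule constants, operating-cost ledger, equipment
#' list and unit prices, all calibrated against the reference facility's
#' printed aggregates.
#'
#' @param scenario `"base"`, `"spinach"` or `"tobacco"`.
#' @return Object of class `tea_config`.
#' @export
scenario_config <- function(scenario = c("base", "spinach", "tobacco")) {
  scenario <- match.arg(scenario)
  p <- variant_params(scenario)
  host <- host_fixture(scenario)
  chain <- build_chain(scenario)
  pr <- reference_prices()
  plan <- upstream_plan(host, p$demand_kg, p$overall_recovery, p$batches,
                        pr$seeds_per_g, pr$seed_per_g)
  structure(list(
    scenario = scenario,
    demand_kg = p$demand_kg,
    batches = p$batches,
    overall_recovery = p$overall_recovery,
    host = host,
    schedule = schedule_fixture(scenario),
    prices = pr,
    chain = chain,
    ledger = ledger_fixture(scenario, plan, chain),
    equipment = equipment_fixture(scenario),
    expected = list(fw_per_batch_kg = p$fw_per_batch_kg,
                    amp_per_batch_kg = p$fw_per_batch_kg *
                      host$expression_g_per_kg / 1000)),
    class = "tea_config")
}

#' @export
print.tea_config <- function(x, ...) {
  cat(sprintf("<tea_config> scenario '%s': %s, %g kg AMP/yr in %d batches\n",
              x$scenario, x$host$name, x$demand_kg, as.integer(x$batches)))
  cat(sprintf("  chain: %s\n",
              paste(vapply(x$chain, function(o) o$name, character(1)),
                    collapse = " -> ")))
  cat(sprintf("  ledger: %d items, equipment: %d items\n",
              NROW(x$ledger), NROW(x$equipment)))
  invisible(x)
}

#' Check a configuration for internal consistency
#'
#' Re-evaluates the cross-relations a valid configuration must satisfy and
#' returns the violations as a character vector (empty when consistent).
#' Never throws on content problems, only on a non-config argument.
#'
#' @param config A `tea_config` (possibly perturbed or read from file).
#' @return Character vector of violation messages, each naming the field.
#' @export
validate_consistency <- function(config) {
  stopifnot(inherits(config, "tea_config"))
  v <- character(0)
  h <- config$host
  if (!is.null(h$expression_g_per_kg) && h$expression_g_per_kg <= 0) {
    v <- c(v, "host.expression_g_per_kg: must be > 0")
  }
  if (!is.null(h$fw_per_plant_g) && h$fw_per_plant_g <= 0) {
    v <- c(v, "host.fw_per_plant_g: must be > 0")
  }
  f <- h$induction_biomass_factor
  if (!is.null(f) && (f <= 0 || f > 1)) {
    v <- c(v, "host.induction_biomass_factor: must lie in (0, 1]")
  }
  for (i in seq_along(config$chain)) {
    op <- config$chain[[i]]
    tr <- op$product_transfer
    bad <- tr < 0 | tr > 1 + 1e-9
    if (any(bad)) {
      v <- c(v, sprintf("chain[%d].product_transfer.%s: outside [0, 1]",
                        i, names(tr)[bad]))
    }
    for (ad in op$added_inputs) {
      if (ad$ratio < 0) {
        v <- c(v, sprintf("chain[%d].added_inputs.%s.ratio: negative",
                          i, ad$name))
      }
    }
  }
  # amp per batch follows fw and expression level
  exp_fw <- config$expected$fw_per_batch_kg
  exp_amp <- config$expected$amp_per_batch_kg
  if (!is.null(exp_fw) && !is.null(exp_amp) &&
      abs(exp_amp - exp_fw * h$expression_g_per_kg / 1000) >
        1e-6 * max(1, exp_amp)) {
    v <- c(v, "expected.amp_per_batch_kg: != fw_per_batch_kg x E / 1000")
  }
  # schedule feasibility: downstream cycle must fit inside the stagger
  s <- config$schedule
  stagger <- s$operating_days_per_year / config$batches
  if (s$downstream_cycle_days > stagger + 1e-9) {
    v <- c(v, "schedule.downstream_cycle_days: exceeds stagger (collision)")
  }
  # ledger arithmetic
  led <- config$ledger
  qp <- !is.na(led$annual_quantity) & !is.na(led$unit_price)
  bad <- qp & abs(led$annual_cost - led$annual_quantity * led$unit_price) >
    1e-6 * pmax(1, led$annual_cost)
  if (any(bad)) {
    v <- c(v, sprintf("ledger.%s.annual_cost: != quantity x unit_price",
                      led$name[bad]))
  }
  if (any(led$annual_cost < 0)) {
    v <- c(v, sprintf("ledger.%s.annual_cost: negative",
                      led$name[led$annual_cost < 0]))
  }
  # chain recovery product vs stated overall recovery
  rec <- 1
  for (op in config$chain) {
    tr <- op$product_transfer
    if ("amp" %in% names(tr)) rec <- rec * tr[["amp"]]
  }
  if (abs(rec - config$overall_recovery) >
      1e-6 * max(1, config$overall_recovery)) {
    v <- c(v, "overall_recovery: != product of chain AMP transfers")
  }
  v
}

#' Randomly perturb a configuration
#'
#' Multiplies selected numeric parameters by independent factors drawn
#' uniformly from `[1 - magnitude, 1 + magnitude]`. Reproducible from
#' `seed`; the global RNG state is left untouched.
#'
#' @param config A `tea_config`.
#' @param seed Integer seed.
#' @param magnitude Perturbation half-width, in (0, 0.5] (0 returns the
#'   config unchanged).
#' @param fields Any of `"prices"` (every ledger item's unit price or pinned
#'   cost), `"transfers"` (chain transfer fractions) and `"host"`
#'   (expression level and per-plant weight).
#' @return The perturbed `tea_config`.
#' @export
perturb_config <- function(config, seed, magnitude,
                           fields = "prices") {
  stopifnot(inherits(config, "tea_config"))
  if (magnitude < 0 || magnitude > 0.5) {
    stop("magnitude must lie in [0, 0.5]", call. = FALSE)
  }
  fields <- match.arg(fields, c("prices", "transfers", "host"),
                      several.ok = TRUE)
  if (magnitude == 0) return(config)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  fac <- function(n) stats::runif(n, 1 - magnitude, 1 + magnitude)

  if ("prices" %in% fields) {
    led <- config$ledger
    f <- fac(NROW(led))
    has_price <- !is.na(led$unit_price)
    led$unit_price[has_price] <- led$unit_price[has_price] * f[has_price]
    led$annual_cost <- led$annual_cost * f
    config$ledger <- led
  }
  if ("transfers" %in% fields) {
    for (i in seq_along(config$chain)) {
      tr <- config$chain[[i]]$product_transfer
      config$chain[[i]]$product_transfer <- tr * fac(length(tr))
    }
  }
  if ("host" %in% fields) {
    config$host$expression_g_per_kg <-
      config$host$expression_g_per_kg * fac(1)
    config$host$fw_per_plant_g <- config$host$fw_per_plant_g * fac(1)
  }
  config
}

#' Emit a scenario configuration file with its manifest
#'
#' Writes the scenario configuration as JSON and returns a manifest
#' recording the calibration notes (which printed aggregate pinned which
#' parameter) and the file checksum. Emission is deterministic: the same
#' scenario always produces a byte-identical file.
#'
#' @param scenario `"base"`, `"spinach"` or `"tobacco"`.
#' @param path Output file path.
#' @return Object of class `tea_fixture_manifest`.
#' @export
emit_config <- function(scenario, path) {
  config <- scenario_config(scenario)
  write_config(config, path)
  structure(list(scenario = scenario,
                 path = path,
                 checksum = unname(tools::md5sum(path)),
                 calibration_notes = fixture_notes(scenario)),
            class = "tea_fixture_manifest")
}

#' Calibration provenance notes for a scenario fixture
#'
#' Each non-printed parameter carries a derivation note; entries are
#' labelled `[PRINTED]` when taken directly from the reference facility's
#' report and `[DERIVED]` when back-calculated from printed aggregates.
#'
#' @param scenario Scenario name.
#' @return Named character vector of notes.
#' @export
fixture_notes <- function(scenario = c("base", "spinach", "tobacco")) {
  scenario <- match.arg(scenario)
  common <- c(
    stage_transfers = "[DERIVED] per-stage transfer fractions from printed stream masses x compositions (11,200/476/236/230/9.06 kg)",
    spray_dry_recovery = "[DERIVED] set to 1.0; diafiltration AMP transfer recalibrated (<0.5% shift) so batches x per-batch output = annual demand exactly",
    powder_salts = "[DERIVED] buffer-salt content of the powder closes the 9.06 kg formulated mass",
    substrate_price = "[DERIVED] $0.01277/plant, inside the printed 1.3 cents rounding, pinning the 41.2% AOC share",
    induction_factor = "[DERIVED] 0.855 = printed annual induction volume / (0.01 L/kg x annual FW)",
    nutrient_ratios = "[DERIVED] 1.50 and 0.503 L/kg FW from printed annual nutrient and waste volumes",
    ledger_residuals = "[DERIVED] labor/utility/resin/membrane items absorb section residuals after pinned shares",
    equipment = "[DERIVED] reference costs calibrated to printed CAPEX section totals")
  extra <- switch(scenario,
    base = c(seed_price = "[PRINTED] $9.50/g, 9,500 seeds/g",
             tray_density = "[PRINTED] 94 seeds per 30 x 50 cm tray",
             fw_per_plant = "[DERIVED] 9,520 kg / 1.22e6 plants per batch"),
    spinach = c(recovery = "[PRINTED] 66% overall recovery, 63% purity",
                fw_per_plant = "[DERIVED] batch FW / 1.08e6 plants"),
    tobacco = c(recovery = "[PRINTED] 58% overall recovery, 92% purity",
                batches = "[PRINTED] 63 seasonal batches of 13,900 plants",
                fw_per_plant = "[DERIVED] batch FW / 13,900 plants"))
  c(common, extra)
}
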