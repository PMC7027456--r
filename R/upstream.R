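#' Host plant parameters
#'
#' Bundles the per-host quantities the upstream model needs. The expression
#' level `expression_g_per_kg` is grams of AMP accumulated per kg of plant
#' fresh weight (FW) at harvest; `tsp_fraction` is the AMP share of total
#' soluble protein (the remaining soluble protein is the host impurity the
#' downstream train must clear). `fw_per_plant_g` is the harvested FW per
#' plant; for indoor hosts it is back-derived from the per-batch biomass and
#' plant count of the reference facility. `induction_biomass_factor` is the
#' fraction of the harvest FW already present at ethanol induction (plants
#' keep growing through the post-induction incubation, so induction sprays
#' less biomass than is eventually harvested).
#'
#' @param name Host display name.
#' @param fw_per_plant_g Harvested fresh weight per plant, g.
#' @param expression_g_per_kg Expression level, g AMP per kg FW.
#' @param tsp_fraction AMP fraction of total soluble protein, in (0, 1].
#' @param seeds_per_tray,plants_per_tray Seeding density per 30 x 50 cm
#'   tray. Germination >= 95 percent is a seed-bank release criterion, not a
#'   yield factor, so plants per tray equals seeds per tray by default.
#' @param growth_days,incubation_days Growth phase and post-induction
#'   incubation durations, days.
#' @param has_alkaloid Whether the host carries a nicotine-class alkaloid
#'   (drives the need for the chromatographic clearance step).
#' @param induction_biomass_factor Fraction in (0, 1].
#' @param nutrient_demand_L_per_kg,nutrient_waste_L_per_kg Hydroponic
#'   nutrient solution demand and non-recirculated (biowaste) volume per kg
#'   FW produced. Zero for field-grown hosts.
#' @param field_grown Field production (no trays, no substrate).
#' @return An object of class `tea_host`.
#' @export
host_params <- function(name,
                        fw_per_plant_g,
                        expression_g_per_kg = 1,
                        tsp_fraction = 0.10,
                        seeds_per_tray = 94,
                        plants_per_tray = seeds_per_tray,
                        growth_days = 35,
                        incubation_days = 6,
                        has_alkaloid = TRUE,
                        induction_biomass_factor = 0.855,
                        nutrient_demand_L_per_kg = 1.50,
                        nutrient_waste_L_per_kg = 0.503,
                        field_grown = FALSE) {
  if (expression_g_per_kg <= 0) stop("expression level must be > 0", call. = FALSE)
  if (fw_per_plant_g <= 0) stop("fw_per_plant_g must be > 0", call. = FALSE)
  if (induction_biomass_factor <= 0 || induction_biomass_factor > 1) {
    stop("induction_biomass_factor must lie in (0, 1]", call. = FALSE)
  }
  if (tsp_fraction <= 0 || tsp_fraction > 1) {
    stop("tsp_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (seeds_per_tray < plants_per_tray || plants_per_tray <= 0) {
    stop("need seeds_per_tray >= plants_per_tray > 0", call. = FALSE)
  }
  structure(list(name = name,
                 fw_per_plant_g = fw_per_plant_g,
                 expression_g_per_kg = expression_g_per_kg,
                 tsp_fraction = tsp_fraction,
                 seeds_per_tray = seeds_per_tray,
                 plants_per_tray = plants_per_tray,
                 growth_days = growth_days,
                 incubation_days = incubation_days,
                 has_alkaloid = has_alkaloid,
                 induction_biomass_factor = induction_biomass_factor,
                 nutrient_demand_L_per_kg = nutrient_demand_L_per_kg,
                 nutrient_waste_L_per_kg = nutrient_waste_L_per_kg,
                 field_grown = field_grown),
            class = "tea_host")
}

#' Size upstream batches from annual demand
#'
#' Works the demand backwards through the downstream losses: the upstream
#' must produce `annual_demand / overall_downstream_recovery` kg of AMP,
#' which at an expression level of E g AMP/kg FW requires
#' `demand / recovery / (E/1000)` kg of fresh weight per year, split evenly
#' over the year's batches.
#'
#' @param annual_demand_kg Formulated AMP demand, kg/yr.
#' @param overall_downstream_recovery Fraction of harvested AMP surviving to
#'   the formulated product, in (0, 1].
#' @param expression_g_per_kg Expression level, g AMP per kg FW.
#' @param batches_per_year Number of manufacturing batches.
#' @return List with `fw_per_batch_kg`, `amp_per_batch_kg`, `annual_fw_kg`
#'   and `annual_upstream_amp_kg`.
#' @export
size_batches <- function(annual_demand_kg, overall_downstream_recovery,
                         expression_g_per_kg, batches_per_year) {
  if (annual_demand_kg <= 0) stop("annual demand must be > 0", call. = FALSE)
  if (overall_downstream_recovery <= 0 || overall_downstream_recovery > 1) {
    stop("overall recovery must lie in (0, 1]", call. = FALSE)
  }
  if (expression_g_per_kg <= 0) stop("expression level must be > 0", call. = FALSE)
  if (batches_per_year < 1) stop("need at least one batch per year", call. = FALSE)
  annual_upstream_amp <- annual_demand_kg / overall_downstream_recovery
  annual_fw <- annual_upstream_amp / (expression_g_per_kg / 1000)
  fw_per_batch <- annual_fw / batches_per_year
  list(fw_per_batch_kg = fw_per_batch,
       amp_per_batch_kg = fw_per_batch * expression_g_per_kg / 1000,
       annual_fw_kg = annual_fw,
       annual_upstream_amp_kg = annual_upstream_amp)
}

#' Per-batch and annual upstream demands for a host
#'
#' Translates the batch biomass requirement into plant counts, trays, seed
#' mass, induction-ethanol solution and hydroponic nutrient volumes.
#'
#' @param host A [host_params()] object.
#' @param annual_demand_kg Formulated AMP demand, kg/yr.
#' @param overall_downstream_recovery Downstream chain recovery fraction.
#' @param batches_per_year Batches per year.
#' @param seeds_per_g Seeds per gram of seed stock.
#' @param seed_price Price per gram of seed stock, $.
#' @return An object of class `tea_upstream_plan`.
#' @export
upstream_plan <- function(host, annual_demand_kg, overall_downstream_recovery,
                          batches_per_year, seeds_per_g = 9500,
                          seed_price = 9.50) {
  stopifnot(inherits(host, "tea_host"))
  sz <- size_batches(annual_demand_kg, overall_downstream_recovery,
                     host$expression_g_per_kg, batches_per_year)
  # tolerance-aware ceiling: exact integer ratios must not round up twice
  ceil_tol <- function(x) ceiling(x - 1e-9 * max(1, abs(x)))
  plants_per_batch <- ceil_tol(sz$fw_per_batch_kg /
                                 (host$fw_per_plant_g / 1000))
  if (host$field_grown) {
    trays_per_batch <- 0
    seeds_per_batch <- plants_per_batch
  } else {
    trays_per_batch <- ceil_tol(plants_per_batch / host$plants_per_tray)
    seeds_per_batch <- trays_per_batch * host$seeds_per_tray
  }
  fw_at_induction <- sz$fw_per_batch_kg * host$induction_biomass_factor
  structure(list(
    host = host,
    annual_demand_kg = annual_demand_kg,
    overall_downstream_recovery = overall_downstream_recovery,
    batches_per_year = batches_per_year,
    fw_per_batch_kg = sz$fw_per_batch_kg,
    amp_per_batch_kg = sz$amp_per_batch_kg,
    annual_fw_kg = sz$annual_fw_kg,
    annual_upstream_amp_kg = sz$annual_upstream_amp_kg,
    plants_per_batch = plants_per_batch,
    trays_per_batch = trays_per_batch,
    seeds_per_batch = seeds_per_batch,
    seed_mass_per_batch_g = seeds_per_batch / seeds_per_g,
    seed_cost_per_year = seeds_per_batch / seeds_per_g * seed_price *
      batches_per_year,
    ethanol_solution_per_batch_L = 0.01 * fw_at_induction,
    nutrient_demand_per_batch_L = host$nutrient_demand_L_per_kg *
      sz$fw_per_batch_kg,
    nutrient_waste_per_batch_L = host$nutrient_waste_L_per_kg *
      sz$fw_per_batch_kg),
    class = "tea_upstream_plan")
}

#' @export
print.tea_upstream_plan <- function(x, ...) {
  cat(sprintf("<tea_upstream_plan> %s, %d batches/yr\n", x$host$name,
              as.integer(x$batches_per_year)))
  cat(sprintf("  FW per batch       %12.4g kg (annual %.4g kg)\n",
              x$fw_per_batch_kg, x$annual_fw_kg))
  cat(sprintf("  AMP per batch      %12.4g kg (annual upstream %.4g kg)\n",
              x$amp_per_batch_kg, x$annual_upstream_amp_kg))
  cat(sprintf("  plants per batch   %12d (%.4g per year)\n",
              as.integer(x$plants_per_batch),
              x$plants_per_batch * x$batches_per_year))
  if (!x$host$field_grown) {
    cat(sprintf("  trays per batch    %12d\n", as.integer(x$trays_per_batch)))
  }
  cat(sprintf("  induction solution %12.4g L/batch (4%% v/v ethanol)\n",
              x$ethanol_solution_per_batch_L))
  invisible(x)
}

#' Induction ethanol demand
#'
#' Expression is switched on by spraying/drenching 0.01 L of 4 percent
#' (v/v) ethanol per kg of FW present at induction. Induction happens before
#' the incubation phase, when the plants carry only
#' `induction_biomass_factor` of their harvest weight.
#'
#' @param plan A [upstream_plan()] object.
#' @param solution_L_per_kg_fw Spray volume per kg FW at induction (L/kg).
#' @return List with `per_batch_L` and `per_year_L` of 4 percent ethanol
#'   solution.
#' @export
induction_demand <- function(plan, solution_L_per_kg_fw = 0.01) {
  stopifnot(inherits(plan, "tea_upstream_plan"))
  f <- plan$host$induction_biomass_factor
  if (f <= 0 || f > 1) stop("induction_biomass_factor must lie in (0, 1]",
                            call. = FALSE)
  per_batch <- solution_L_per_kg_fw * plan$fw_per_batch_kg * f
  list(per_batch_L = per_batch,
       per_year_L = per_batch * plan$batches_per_year)
}

#' Seed and tray demand
#'
#' Trays per batch, annual seed mass and annual seed cost. One gram of seed
#' stock holds `seeds_per_g` seeds; every tray is sown at the host's full
#' seeding density.
#'
#' @inheritParams induction_demand
#' @param seeds_per_g Seeds per gram of seed stock.
#' @param seed_price $ per gram of seed stock.
#' @return List with `trays_per_batch`, `seeds_per_year`, `seed_g_per_year`,
#'   `seed_cost_per_year` and `plants_per_year`.
#' @export
seed_and_tray_demand <- function(plan, seeds_per_g = 9500, seed_price = 9.50) {
  stopifnot(inherits(plan, "tea_upstream_plan"))
  seeds_per_year <- plan$seeds_per_batch * plan$batches_per_year
  list(trays_per_batch = plan$trays_per_batch,
       seeds_per_year = seeds_per_year,
       seed_g_per_year = seeds_per_year / seeds_per_g,
       seed_cost_per_year = seeds_per_year / seeds_per_g * seed_price,
       plants_per_year = plan$plants_per_batch * plan$batches_per_year)
}
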