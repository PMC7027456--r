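cfg <- scenario_config("base")

test_that("purchase-price sensitivity matches the reference responses", {
  sub <- price_sensitivity(cfg, "soilless plant substrate", c(-0.3, 0, 0.3))
  expect_equal(sub$cogs_change_pct, c(-12.36, 0, 12.36), tolerance = 1e-3)
  elu <- price_sensitivity(cfg, "chromatography elution buffer",
                           c(-0.3, 0.3))
  expect_equal(round(elu$cogs_change_pct, 2), c(-0.41, 0.41))
  expect_error(price_sensitivity(cfg, "moon dust"), "unknown ledger item")
})

test_that("the COGS response to a price change is exactly linear in delta", {
  led <- cfg$ledger
  aoc <- sum(led$annual_cost)
  set.seed(9)
  for (i in 1:10) {
    item <- sample(led$name, 1)
    d <- runif(1, -0.5, 0.5)
    share <- led$annual_cost[led$name == item] / aoc
    got <- price_sensitivity(cfg, item, d)$cogs_change_pct
    expect_equal(got, 100 * d * share, tolerance = 1e-9)
  }
})

test_that("COGS falls with expression level with strongly diminishing returns", {
  scan <- expression_scan(cfg, c(0.5, 1, 2, 3, 4, 5))
  expect_true(all(diff(scan$cogs_per_g) < 0))
  d_low <- scan$cogs_per_g[1] - scan$cogs_per_g[2]   # 0.5 -> 1 g/kg
  d_high <- scan$cogs_per_g[5] - scan$cogs_per_g[6]  # 4 -> 5 g/kg
  expect_gte(d_low, 10 * d_high)
  # biomass requirement follows fw = demand / (recovery x E x batches)
  expect_equal(scan$fw_per_batch_kg,
               cfg$demand_kg / cfg$overall_recovery /
                 (scan$expression_g_per_kg / 1000) / cfg$batches,
               tolerance = 1e-9)
  expect_equal(signif(scan$fw_per_batch_kg[scan$expression_g_per_kg == 1], 3),
               9520)
  expect_error(expression_scan(cfg, c(2, 1)), "strictly increasing")
})

test_that("with only variable upstream costs, doubling E halves the per-gram cost", {
  cfg2 <- cfg
  cfg2$ledger <- cfg2$ledger[cfg2$ledger$section == "upstream" &
                               cfg2$ledger$scale_with == "biomass", ]
  scan <- expression_scan(cfg2, c(1, 2))
  expect_equal(scan$cogs_per_g[2], scan$cogs_per_g[1] / 2, tolerance = 1e-12)
})

test_that("the downstream COGS share falls as annual production grows", {
  scan <- production_scan(cfg, seq(100, 1000, by = 100))
  expect_true(all(diff(scan$downstream_share_pct) < 0))
  # identity point: demand x1 recovers the base COGS exactly
  expect_equal(scan$cogs_per_g[scan$annual_demand_kg == 500],
               run_pipeline(cfg)$report$cogs_per_g, tolerance = 1e-12)
  # upstream per-gram cost is nearly flat (linear platform scalability)
  up <- scan$cogs_upstream_per_g
  expect_lt(max(up) / min(up) - 1, 0.15)
  expect_error(production_scan(cfg, c(-5, 10)), "positive")
})

test_that("named scenarios run end to end with their reference economics", {
  sp <- run_scenario("spinach")
  expect_equal(sp$report$cogs_per_g, 4.92, tolerance = 1e-6)
  expect_equal(sp$report$capex_total / 1e6, 46.5, tolerance = 1e-6)
  expect_equal(sp$config$schedule$downstream_cycle_days, 0.67)

  tb <- run_scenario("tobacco")
  expect_equal(tb$report$cogs_per_g, 3.00, tolerance = 0.005)
  expect_equal(tb$report$capex_total / 1e6, 27.5, tolerance = 1e-6)
  expect_equal(tb$schedule$batches_per_year, 63)
  expect_equal(tb$plan$plants_per_batch, 13900)

  # regression identity: the base scenario equals the directly-run pipeline
  direct <- run_pipeline(scenario_config("base"))
  named <- run_scenario("base")
  expect_equal(named$report$cogs_per_g, direct$report$cogs_per_g)
  expect_equal(named$quality$formulated_mass_per_batch_kg,
               direct$quality$formulated_mass_per_batch_kg)
})

test_that("reusing the substrate once cuts operating costs by about a fifth", {
  led <- cfg$ledger
  aoc0 <- sum(led$annual_cost)
  i <- led$name == "soilless plant substrate"
  led$annual_cost[i] <- led$annual_cost[i] / 2
  led$unit_price[i] <- led$unit_price[i] / 2
  reduction <- 100 * (aoc0 - sum(led$annual_cost)) / aoc0
  expect_equal(round(reduction), 21)
})

test_that("cost of use converts production cost to treatment cost", {
  cu <- cost_of_use(6.88, "meat_product", c(2, 10))
  expect_equal(cu$cost_low, 2 * 6.88 / 1000)
  expect_equal(cu$cost_high, 10 * 6.88 / 1000)
  expect_match(cu$cost_unit, "kg food")
  # overlaps the standard-treatment comparator band
  expect_lt(cu$cost_low, cu$standard_treatment_band[["high"]])
  expect_gt(cu$cost_high, cu$standard_treatment_band[["low"]])

  wash <- cost_of_use(6.88, "carcass_spray", c(2, 10))
  expect_match(wash$cost_unit, "L wash")
  expect_equal(cost_of_use(6.88, "meat_product", c(0, 0))$cost_high, 0)
  expect_error(cost_of_use(6.88, "sous_vide"))
})
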