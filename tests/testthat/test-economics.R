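base_cfg <- scenario_config("base")

test_that("the base equipment list reproduces the reference CAPEX split", {
  cap <- capex(base_cfg$equipment)
  expect_equal(cap$by_section[["upstream"]] / 1e6, 19.1, tolerance = 1e-6)
  expect_equal(cap$by_section[["downstream"]] / 1e6, 31.0, tolerance = 1e-6)
  expect_equal(cap$total / 1e6, 50.1, tolerance = 1e-6)
  # downstream dominates the capital investment
  expect_equal(round(100 * cap$by_section[["downstream"]] / cap$total), 62)
})

test_that("equipment cost follows the capacity-exponent rule", {
  item <- equipment_item("skid", "downstream", 1e6,
                         reference_size = 10, actual_size = 10,
                         scaling_exponent = 0.6,
                         installation_multiplier = 3)
  expect_equal(capex(item)$total, 3e6)
  item$actual_size <- 20
  expect_equal(capex(item)$total, 3e6 * 2^0.6)
  item$actual_size <- -1
  expect_error(capex(item), "> 0")
  expect_error(equipment_item("x", "upstream", 0), "> 0")
})

test_that("the base ledger reproduces the reference OPEX rollup", {
  op <- opex(base_cfg$ledger)
  expect_equal(op$aoc / 1e6, 3.44, tolerance = 1e-9)
  expect_equal(op$by_section[["upstream"]] / 1e6, 2.01, tolerance = 1e-9)
  expect_equal(op$by_section[["downstream"]] / 1e6, 1.43, tolerance = 1e-9)
  # upstream carries 58% of operating costs
  expect_equal(round(100 * op$by_section[["upstream"]] / op$aoc), 58)
  # seeding operation dominates upstream OPEX at 79%
  led <- base_cfg$ledger
  seeding <- sum(led$annual_cost[led$operation == "seeding"])
  expect_equal(100 * seeding / op$by_section[["upstream"]], 79,
               tolerance = 1e-9)
  # chromatography and UF/DF dominate downstream OPEX (38% and 35%)
  chrom <- sum(led$annual_cost[led$operation == "chromatography"])
  ufdf <- sum(led$annual_cost[led$operation == "ufdf"])
  expect_equal(100 * chrom / op$by_section[["downstream"]], 38,
               tolerance = 1e-9)
  expect_equal(100 * ufdf / op$by_section[["downstream"]], 35,
               tolerance = 1e-9)
  # downstream labor-dependent costs are 18.5% of AOC
  ds_labor <- sum(led$annual_cost[led$section == "downstream" &
                                    led$category == "labor"])
  expect_equal(100 * ds_labor / op$aoc, 18.5, tolerance = 1e-9)
})

test_that("ledger validation catches broken arithmetic and empty categories", {
  led <- base_cfg$ledger
  led$annual_cost[1] <- led$annual_cost[1] * 2  # break qty x price
  expect_error(opex(led), "quantity x price")

  only_labor <- cost_item("crew", "upstream", "labor", annual_cost = 1000)
  op <- opex(only_labor)
  expect_equal(op$by_category[["consumable"]], 0)
  expect_equal(op$by_category[["labor"]], 1000)
})

test_that("COGS is annual operating cost per gram with section attribution", {
  cg <- cogs(3.44e6, 500, c(upstream = 2.01e6, downstream = 1.43e6))
  expect_equal(cg$cogs_per_g, 6.88)
  expect_equal(cg$cogs_upstream_per_g, 4.02)
  expect_equal(cg$cogs_downstream_per_g, 2.86)
  expect_equal(cogs(1e6, 1000)$cogs_per_g, 1.00)
  # calibrated spinach ledger: $2.46M over 500 kg
  expect_equal(cogs(2.46e6, 500)$cogs_per_g, 4.92)
  expect_error(cogs(1e6, 0), "demand")
  # homogeneity of degree -1 in demand
  set.seed(5)
  for (i in 1:10) {
    aoc <- runif(1, 1e5, 1e7); d <- runif(1, 10, 1000); k <- runif(1, 0.1, 10)
    expect_equal(cogs(aoc, k * d)$cogs_per_g, cogs(aoc, d)$cogs_per_g / k,
                 tolerance = 1e-12)
  }
})

test_that("report shares are complete and the top-10 items carry ~90% of AOC", {
  rep <- cost_report(base_cfg$equipment, base_cfg$ledger, 500)
  expect_equal(sum(rep$shares$opex_section_pct), 100, tolerance = 1e-9)
  expect_equal(sum(rep$shares$capex_section_pct), 100, tolerance = 1e-9)
  expect_equal(sum(rep$shares$category_pct), 100, tolerance = 1e-9)
  expect_equal(sum(rep$shares$item_pct), 100, tolerance = 1e-9)
  top10 <- sum(sort(rep$opex$items$annual_cost, decreasing = TRUE)[1:10])
  expect_equal(100 * top10 / rep$aoc, 90, tolerance = 0.005)
  # substrate alone is 41.2% of AOC at ~1.3 cents per plant
  led <- rep$opex$items
  sub <- led[led$name == "soilless plant substrate", ]
  expect_equal(100 * sub$annual_cost / rep$aoc, 41.2, tolerance = 1e-3)
  expect_equal(sub$unit_price, 0.013, tolerance = 0.02)
  # COGS split matches the section totals exactly
  expect_equal(rep$cogs_upstream_per_g + rep$cogs_downstream_per_g,
               rep$cogs_per_g, tolerance = 1e-12)
})

test_that("depreciation is available as a report line but outside COGS", {
  rep <- cost_report(base_cfg$equipment, base_cfg$ledger, 500)
  dep <- straight_line_depreciation(rep$capex_total)
  expect_gt(dep, 0)
  expect_equal(rep$cogs_per_g, rep$aoc / 5e5, tolerance = 1e-12)
})
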