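base_rec <- (500 / 91) / 9.52  # overall downstream recovery of the base chain

test_that("batch sizing works demand back through the downstream loss", {
  sz <- size_batches(500, base_rec, 1, 91)
  expect_equal(sz$fw_per_batch_kg, 9520, tolerance = 1e-9)
  expect_equal(signif(sz$annual_fw_kg, 3), 866000)
  expect_equal(sz$annual_upstream_amp_kg, 500 / base_rec)
  expect_equal(sz$amp_per_batch_kg, 9.52, tolerance = 1e-9)

  # degenerate unit case: no loss, 1 kg AMP per kg FW, one batch
  expect_equal(size_batches(123, 1, 1000, 1)$fw_per_batch_kg, 123)

  expect_error(size_batches(-1, 0.5, 1, 91), "demand")
  expect_error(size_batches(500, 0, 1, 91), "recovery")
})

test_that("the spinach host needs ~10% fewer, slightly smaller plants", {
  sz <- size_batches(500, 0.66, 1, 91)
  expect_equal(sz$fw_per_batch_kg, 8325, tolerance = 1e-4)
  host <- host_params("S. oleracea",
                      fw_per_plant_g = sz$fw_per_batch_kg / 1.08e6 * 1000,
                      has_alkaloid = FALSE)
  plan <- upstream_plan(host, 500, 0.66, 91)
  expect_equal(plan$plants_per_batch, 1.08e6)
})

test_that("induction ethanol demand follows the biomass present at induction", {
  host <- host_params("N. benthamiana", fw_per_plant_g = 9520 / 1.22e6 * 1000)
  plan <- upstream_plan(host, 500, base_rec, 91)
  eth <- induction_demand(plan)
  expect_equal(eth$per_year_L, 7410, tolerance = 5e-4)

  # factor = 1: 0.01 L per kg of the full 1,000 kg
  h1 <- host_params("toy", fw_per_plant_g = 1000,
                    induction_biomass_factor = 1)
  p1 <- upstream_plan(h1, 1, 1, 1)  # 1,000 kg FW in one batch
  expect_equal(p1$fw_per_batch_kg, 1000)
  expect_equal(induction_demand(p1)$per_batch_L, 10)

  # linearity in the induction factor
  h2 <- host_params("toy", fw_per_plant_g = 1000,
                    induction_biomass_factor = 0.5)
  p2 <- upstream_plan(h2, 1, 1, 1)
  expect_equal(induction_demand(p2)$per_year_L,
               induction_demand(p1)$per_year_L / 2)

  expect_error(host_params("bad", 1, induction_biomass_factor = 1.2),
               "induction_biomass_factor")
})

test_that("seed and tray demand matches the reference facility", {
  host <- host_params("N. benthamiana", fw_per_plant_g = 9520 / 1.22e6 * 1000)
  plan <- upstream_plan(host, 500, base_rec, 91)
  sd <- seed_and_tray_demand(plan)
  expect_equal(sd$trays_per_batch, 12979)
  expect_equal(sd$seed_cost_per_year, 111000, tolerance = 0.001)
  expect_equal(sd$plants_per_year, 111e6, tolerance = 0.001)

  # 94 plants fill exactly one tray
  tiny <- host_params("toy", fw_per_plant_g = 1000,
                      expression_g_per_kg = 1000)
  p <- upstream_plan(tiny, 94, 1, 1)  # 94 kg FW -> 94 plants
  expect_equal(p$trays_per_batch, 1)
})

test_that("upstream demands scale inversely with expression and recovery and
           linearly with demand", {
  set.seed(11)
  for (i in 1:25) {
    d <- runif(1, 10, 1000); rec <- runif(1, 0.2, 1)
    e <- runif(1, 0.2, 5); b <- sample(1:120, 1); k <- runif(1, 1.5, 4)
    f0 <- size_batches(d, rec, e, b)$fw_per_batch_kg
    expect_equal(size_batches(d, rec, e * k, b)$fw_per_batch_kg, f0 / k,
                 tolerance = 1e-12)
    expect_equal(size_batches(d, min(rec * k, 1), e, b)$fw_per_batch_kg,
                 f0 * rec / min(rec * k, 1), tolerance = 1e-12)
    expect_equal(size_batches(2 * d, rec, e, b)$fw_per_batch_kg, 2 * f0,
                 tolerance = 1e-12)
  }
  # doubling demand doubles every continuous upstream quantity
  host <- host_params("N. benthamiana", fw_per_plant_g = 9520 / 1.22e6 * 1000)
  p1 <- upstream_plan(host, 500, base_rec, 91)
  p2 <- upstream_plan(host, 1000, base_rec, 91)
  for (fld in c("fw_per_batch_kg", "amp_per_batch_kg", "annual_fw_kg",
                "ethanol_solution_per_batch_L", "nutrient_demand_per_batch_L",
                "nutrient_waste_per_batch_L")) {
    expect_equal(p2[[fld]], 2 * p1[[fld]], tolerance = 1e-12)
  }
  expect_equal(p2$plants_per_batch, 2 * p1$plants_per_batch, tolerance = 1e-6)
})
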