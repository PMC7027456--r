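test_that("chain variants include or omit the nicotine-clearance step", {
  base <- build_chain("base")
  spinach <- build_chain("spinach")
  tobacco <- build_chain("tobacco")
  op_names <- function(ch) vapply(ch, function(o) o$name, character(1))
  expect_length(base, 5)
  expect_length(spinach, 4)
  expect_length(tobacco, 5)
  expect_true(any(grepl("cation exchange", op_names(base))))
  expect_false(any(grepl("cation exchange", op_names(spinach))))
  expect_true(any(grepl("cation exchange", op_names(tobacco))))
  expect_error(build_chain("maize"))
})

test_that("variant chains close on their stated recovery and purity", {
  cases <- list(list(v = "spinach", rec = 0.66, pur = 63),
                list(v = "tobacco", rec = 0.58, pur = 92))
  for (cs in cases) {
    p <- variant_params(cs$v)
    host <- host_params("h", fw_per_plant_g = 10,
                        has_alkaloid = p$include_cex)
    q <- quality_metrics(run_chain(build_chain(cs$v),
                                   harvest_stream(p$fw_per_batch_kg, host)))
    expect_equal(q$overall_recovery, cs$rec, tolerance = 1e-6)
    expect_equal(q$protein_basis_purity_pct, cs$pur, tolerance = 1e-6)
  }
})

test_that("base-case quality metrics match the reference facility", {
  host <- host_params("N. benthamiana", fw_per_plant_g = 9520 / 1.22e6 * 1000)
  q <- quality_metrics(run_chain(build_chain("base"),
                                 harvest_stream(9520, host)))
  expect_equal(q$formulated_mass_per_batch_kg, 9.06, tolerance = 1e-6)
  # protein-basis purity: 100 x 60.64 / (60.64 + 5.32) ~ 92%
  expect_equal(round(q$protein_basis_purity_pct), 92)
  # 42% loss across extraction, purification and formulation
  expect_equal(round(100 * (1 - q$overall_recovery)), 42)
})

test_that("identity chains preserve recovery and purity", {
  ident <- unit_op("identity", default_transfer = 1)
  s <- stream(c(water = 100, amp = 5, impurity = 2))
  q <- quality_metrics(run_chain(list(ident, ident), s))
  expect_equal(q$overall_recovery, 1)
  expect_equal(q$protein_basis_purity_pct, 100 * 5 / 7)

  sink_op <- unit_op("sink", default_transfer = 0)
  expect_error(quality_metrics(run_chain(list(sink_op), s)), "zero")
})

test_that("deleting the chromatography stage raises impurity and recovery", {
  host <- host_params("N. benthamiana", fw_per_plant_g = 9520 / 1.22e6 * 1000)
  harvest <- harvest_stream(9520, host)
  chain <- build_chain("base")
  with_cex <- quality_metrics(run_chain(chain, harvest))
  without <- quality_metrics(run_chain(chain[-3], harvest))
  expect_gt(without$impurity_mass_per_batch_kg,
            with_cex$impurity_mass_per_batch_kg)
  expect_gt(without$overall_recovery, with_cex$overall_recovery)
  expect_lt(without$protein_basis_purity_pct,
            with_cex$protein_basis_purity_pct)
})

test_that("per-batch output times batch count meets annual demand", {
  for (v in c("base", "spinach", "tobacco")) {
    p <- variant_params(v)
    host <- host_params("h", fw_per_plant_g = 10)
    q <- quality_metrics(run_chain(build_chain(v),
                                   harvest_stream(p$fw_per_batch_kg, host)))
    expect_equal(q$amp_mass_per_batch_kg * p$batches, p$demand_kg,
                 tolerance = 0.005)
  }
})
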