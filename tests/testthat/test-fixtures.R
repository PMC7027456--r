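test_that("emitted configurations are deterministic and self-consistent", {
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  m1 <- emit_config("base", f1)
  m2 <- emit_config("base", f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(m1$checksum, m2$checksum)
  expect_identical(m1$checksum, unname(tools::md5sum(f1)))
  expect_s3_class(m1, "tea_fixture_manifest")
  # every calibration note is labelled with its provenance
  expect_true(all(grepl("^\\[(PRINTED|DERIVED)\\]", m1$calibration_notes)))
  unlink(c(f1, f2))

  for (s in c("base", "spinach", "tobacco")) {
    expect_length(validate_consistency(scenario_config(s)), 0)
  }
})

test_that("the validator names the offending field", {
  cfg <- scenario_config("base")
  cfg$chain[[1]]$product_transfer[["amp"]] <- 1.2
  v <- validate_consistency(cfg)
  expect_true(any(grepl("chain\\[1\\].product_transfer.amp", v)))

  cfg2 <- scenario_config("base")
  cfg2$ledger$annual_cost[1] <- cfg2$ledger$annual_cost[1] + 1000
  v2 <- validate_consistency(cfg2)
  expect_true(any(grepl("ledger.*annual_cost", v2)))

  cfg3 <- scenario_config("base")
  cfg3$schedule$downstream_cycle_days <- 10
  expect_true(any(grepl("collision", validate_consistency(cfg3))))
})

test_that("perturbation is reproducible and vanishes at zero magnitude", {
  cfg <- scenario_config("base")
  p1 <- perturb_config(cfg, seed = 0, magnitude = 0.2)
  p2 <- perturb_config(cfg, seed = 0, magnitude = 0.2)
  expect_identical(p1, p2)
  expect_false(identical(p1$ledger$annual_cost, cfg$ledger$annual_cost))
  expect_identical(perturb_config(cfg, seed = 0, magnitude = 0), cfg)
  expect_error(perturb_config(cfg, 0, 0.7), "magnitude")
})

test_that("the validator agrees with an independent re-evaluation of each rule
           on 1,000 randomly perturbed configurations", {
  cfg <- scenario_config("base")
  for (i in 1:1000) {
    mag <- (i %% 10 + 1) / 20  # magnitudes 0.05 ... 0.5
    what <- c("prices", "transfers", "host")[(i %% 3) + 1]
    p <- perturb_config(cfg, seed = i, magnitude = mag, fields = what)
    v <- validate_consistency(p)

    # rule 1: transfer fractions inside [0, 1]
    out_of_range <- FALSE
    for (op in p$chain) {
      tr <- op$product_transfer
      if (any(tr < 0 | tr > 1 + 1e-9)) out_of_range <- TRUE
    }
    expect_equal(any(grepl("outside \\[0, 1\\]", v)), out_of_range)

    # rule 2: stated overall recovery equals the chain product
    rec <- 1
    for (op in p$chain) {
      if ("amp" %in% names(op$product_transfer)) {
        rec <- rec * op$product_transfer[["amp"]]
      }
    }
    mismatch <- abs(rec - p$overall_recovery) >
      1e-6 * max(1, p$overall_recovery)
    expect_equal(any(grepl("overall_recovery", v)), mismatch)

    # rule 3: ledger arithmetic (price perturbations scale price and cost
    # together, so they must never trip this rule)
    led <- p$ledger
    qp <- !is.na(led$annual_quantity) & !is.na(led$unit_price)
    bad <- any(qp & abs(led$annual_cost -
                          led$annual_quantity * led$unit_price) >
                 1e-6 * pmax(1, led$annual_cost))
    expect_equal(any(grepl("quantity x unit_price", v)), bad)
  }
})

test_that("COGS moves no further than a uniform all-price perturbation", {
  cfg <- scenario_config("base")
  base_cogs <- sum(cfg$ledger$annual_cost) / (cfg$demand_kg * 1000)
  for (s in 1:50) {
    p <- perturb_config(cfg, seed = s, magnitude = 0.10, fields = "prices")
    cg <- sum(p$ledger$annual_cost) / (p$demand_kg * 1000)
    expect_lte(abs(cg - base_cogs) / base_cogs, 0.10 + 1e-12)
  }
})

test_that("the emitted base config drives the pipeline to the reference COGS", {
  f <- tempfile(fileext = ".json")
  emit_config("base", f)
  run <- run_pipeline(read_config(f))
  expect_equal(run$report$cogs_per_g, 6.88, tolerance = 1e-9)
  led <- run$report$opex$items
  top10 <- sum(led$annual_cost[1:10])
  expect_equal(100 * top10 / run$report$aoc, 90, tolerance = 0.005)
  unlink(f)
})
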