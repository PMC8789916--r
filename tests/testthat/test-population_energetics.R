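test_that("cell-specific rates divide volumetric rate by functional cells", {
  expect_equal(cell_specific_rate(0.1, 500), 0.2)
  expect_equal(cell_specific_rate(0.1, 500, functional_fraction = 0.1), 2)
  expect_equal(cell_specific_rate(0, 500), 0)
  expect_error(cell_specific_rate(0.1, 0), "zero functional")
  expect_error(cell_specific_rate(0.1, 500, functional_fraction = 0),
               "functional_fraction")
})

test_that("per-cell energy turnover is |dG| x rate / abundance", {
  expect_equal(energy_turnover(-100, 1e-16, 500), 2e-17)
  expect_equal(energy_turnover(-100, 0, 500), 0)
  set.seed(5)
  for (i in 1:20) {
    dg <- -runif(1, 10, 200); r <- runif(1, 1e-18, 1e-12)
    n <- runif(1, 16, 1e5)
    expect_equal(energy_turnover(dg, r, n), abs(dg) * r / n)
  }
})

test_that("maintenance rate and per-cell threshold are consistent", {
  expect_equal(maintenance_rate(1e-14, 500, -105), 1e-14 * 500 / 105)
  expect_equal(maintenance_rate(1e-14, 0, -105), 0)
  expect_equal(maintenance_rate(1e-14, 500, -52.5),
               2 * maintenance_rate(1e-14, 500, -105))
  expect_error(maintenance_rate(1e-14, 500, 0), "dG")

  # thresholds anchored by the repair cost at 100 C
  expect_equal(threshold_cell_rate(1e-14, -105), 1e-14 / 105 * 1e15)
  expect_equal(round(threshold_cell_rate(1e-14, -105), 1), 0.1)
  expect_equal(round(threshold_cell_rate(1e-14, -43), 1), 0.2)
  expect_equal(threshold_cell_rate(2e-14, -105),
               2 * threshold_cell_rate(1e-14, -105))

  # round trip: threshold x |dG| recovers the cost (fmol -> mol)
  expect_equal(threshold_cell_rate(1e-14, -105) * 105 / 1e15, 1e-14)

  # volumetric and per-cell forms agree: maintenance/abundance = threshold
  set.seed(9)
  for (i in 1:10) {
    cost <- 10^runif(1, -16, -13); n <- runif(1, 16, 1e4)
    dg <- -runif(1, 20, 200)
    expect_equal(maintenance_rate(cost, n, dg) / n * 1e15,
                 threshold_cell_rate(cost, dg))
  }
})

test_that("repair cost is calibrated, Arrhenius, and genome-linear", {
  p <- repair_cost_params()
  expect_equal(repair_cost(100, p), 1e-14)
  # strictly increasing in temperature
  temps <- seq(40, 120, by = 5)
  cost <- repair_cost(temps, p)
  expect_true(all(diff(cost) > 0))
  # log cost is convex in 1/T (log-sum-exp of affine functions)
  x <- rev(1 / (temps + 273.15))    # increasing in 1/T
  lc <- rev(log(cost))
  slopes <- diff(lc) / diff(x)
  expect_true(all(diff(slopes) >= -1e-6 * abs(slopes[-1])))
  # doubling genome size doubles the depurination term only
  dna_term <- repair_cost(80, p, genome_size_mb = 2 * p$genome_size_mb) -
    repair_cost(80, p)
  expect_equal(repair_cost(80, p, genome_size_mb = 3 * p$genome_size_mb) -
                 repair_cost(80, p, genome_size_mb = p$genome_size_mb),
               2 * dna_term)
  expect_error(repair_cost_params(replacement_fraction = 1.5),
               "replacement_fraction")
})

test_that("biomass turnover time follows the carbon budget", {
  # 500 cells at face value, 22 fg C, 1e-13 mol cm^-3 d^-1, stoich 2, yield 0.01
  tb <- biomass_turnover_time(500, 1e-13, correct_recovery = FALSE)
  expect_equal(tb, 500 * 22e-15 / 12 / (1e-13 * 2 * 0.01))
  expect_equal(tb, 458.33, tolerance = 1e-4)

  # higher yield and smaller functional fraction shorten turnover
  expect_equal(biomass_turnover_time(500, 1e-13, growth_yield = 0.2,
                                     correct_recovery = FALSE), tb / 20)
  expect_equal(biomass_turnover_time(500, 1e-13, functional_fraction = 0.1,
                                     correct_recovery = FALSE), tb / 10)
  # recovery correction scales the standing biomass up by 1/0.25
  expect_equal(biomass_turnover_time(500, 1e-13), tb / 0.25)
  # proportionality in abundance and cell carbon, inverse in rate
  expect_equal(biomass_turnover_time(1000, 1e-13, correct_recovery = FALSE),
               2 * tb)
  expect_equal(biomass_turnover_time(500, 2e-13, correct_recovery = FALSE),
               tb / 2)
  expect_equal(biomass_turnover_time(500, 1e-13, cell_carbon_fg = 44,
                                     correct_recovery = FALSE), 2 * tb)
  expect_error(biomass_turnover_time(500, 0), "rate")
})

test_that("specific turnover is the reciprocal turnover time", {
  expect_equal(specific_turnover(1), 1)
  expect_equal(specific_turnover(458), 1 / 458, tolerance = 1e-12)
  tb <- 123.4
  expect_equal(1 / specific_turnover(tb), tb)
  expect_error(specific_turnover(0), "t_b")
})

test_that("the per-cell table censors sub-MQL cell counts as bounds", {
  tab <- per_cell_table(depth_mbsf = c(700, 900),
                        rate_pmol_cm3_d = c(0.3, 0.3),
                        abundance_cells_cm3 = c(500, 5),
                        dG_kj_mol = c(-105, -105), temp_C = c(72, 92))
  expect_false(tab$abundance_censored[1])
  expect_true(tab$abundance_censored[2])
  # censored row evaluated at the 16 cells quantification limit
  expect_equal(tab$cell_rate_fmol[2], cell_specific_rate(0.3, 16))
  expect_true(all(tab$repair_threshold_fmol > 0))
})
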