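test_that("linear geothermal temperature model", {
  expect_equal(insitu_temperature(0, surface_temp_C = 7), 7)
  expect_equal(insitu_temperature(920, 100, 2), 94)
  expect_equal(insitu_temperature(1073, 110, 2), 120, tolerance = 0.01)
  expect_error(insitu_temperature(-5), "depth")
})

test_that("activity coefficients follow the extended Debye-Hueckel form", {
  # infinite dilution
  expect_equal(activity_coefficient(-2, 0, 4), 1)
  expect_equal(activity_coefficient(1, 0, 9, bdot = 0.041), 1)
  # neutral species without a salting coefficient
  expect_equal(activity_coefficient(0, 0.64, 0, bdot = 0), 1)
  # closed-form hand evaluation at 25 C (A = 0.5092, B = 0.3283)
  I <- 0.64
  by_hand <- 10^(-0.5092 * 4 * sqrt(I) / (1 + 0.3283 * 4 * sqrt(I)))
  expect_equal(activity_coefficient(-2, I, 4, bdot = 0, temp_C = 25),
               by_hand, tolerance = 1e-12)
  # gamma -> 1 monotonically as I -> 0 for a charged species, bdot = 0
  Is <- c(0.64, 0.3, 0.1, 0.03, 0.01, 1e-4, 1e-8)
  g <- activity_coefficient(-1, Is, 4)
  expect_true(all(diff(g) > 0))
  expect_equal(g[length(g)], 1, tolerance = 1e-3)
  expect_error(dh_coefficients(200), "0-150")
})

test_that("species activities apply coefficients and detection floors", {
  act <- species_activities(c("SO4-2" = 1e-2, "CH4" = 1e-3, "HS-" = 0),
                            ionic_strength = 0.64, temp_C = 100,
                            below_detection = "HS-")
  expect_equal(unname(act["CH4"]), 1e-3)     # neutral, ideal
  expect_lt(act["SO4-2"], 1e-2)              # divalent ion suppressed
  gam_hs <- activity_coefficient(-1, 0.64, 3.5, 0.041, 100)
  expect_equal(unname(act["HS-"]), 1e-7 * gam_hs)
  expect_error(species_activities(c(1e-3), 0.64), "named")
})

test_that("activity quotient multiplies activities to stoichiometric powers", {
  aom <- catabolic_reactions()$AOM
  expect_equal(activity_quotient(aom, c("CH4" = 1, "SO4-2" = 1,
                                        "HCO3-" = 1, "HS-" = 1)), 1)
  # hand product: Q = (1e-3 * 1e-7) / (1e-3 * 1e-2) = 1e-5
  a <- c("CH4" = 1e-3, "SO4-2" = 1e-2, "HCO3-" = 1e-3, "HS-" = 1e-7)
  expect_equal(activity_quotient(aom, a), 1e-5)
  # doubling a nu = -1 reactant halves Q
  a2 <- a; a2["CH4"] <- 2e-3
  expect_equal(activity_quotient(aom, a2), activity_quotient(aom, a) / 2)
  expect_error(activity_quotient(aom, a[-1]), "missing activities")
  a0 <- a; a0["SO4-2"] <- 0
  expect_error(activity_quotient(aom, a0), "reactant")
  ap <- a; ap["HS-"] <- 0
  expect_equal(activity_quotient(aom, ap), 0)
})

test_that("Gibbs energy is dG0 plus RT ln Q", {
  expect_equal(gibbs_energy(-50, 300, 1), -50)
  expect_equal(gibbs_energy(0, 373.15, 10), 0.008314 * 373.15 * log(10))
  # slope in ln Q is RT
  qs <- exp(seq(-5, 5, by = 1))
  dg <- gibbs_energy(-50, 350, qs)
  expect_equal(diff(dg) / diff(log(qs)), rep(0.008314 * 350, length(qs) - 1))
  # reversing a reaction negates ln Q, flipping the RT ln Q term
  aom <- catabolic_reactions()$AOM
  a <- c("CH4" = 1e-3, "SO4-2" = 1e-2, "HCO3-" = 1e-3, "HS-" = 1e-7)
  rev <- reaction_spec("AOM_rev", -aom$stoichiometry)
  expect_equal(log(activity_quotient(rev, a)),
               -log(activity_quotient(aom, a)))
  expect_error(gibbs_energy(-50, 300, 0), "Q")
})

test_that("the five packaged reactions balance elements and charge", {
  rx <- catabolic_reactions()
  expect_setequal(names(rx),
                  c("AOM", "SR_acetate", "SR_H2", "MG_acetate", "MG_H2"))
  for (r in rx) {
    bal <- check_reaction_balance(r)
    expect_equal(unname(bal), rep(0, length(bal)), label = r$name)
  }
})

test_that("the packaged anchor reproduces the in-situ reaction energies", {
  rx <- catabolic_reactions()
  anchor <- attr(rx, "anchor_conditions")
  conc <- unlist(anchor$conc_mol_l)
  conc[["H+"]] <- 10^(-anchor$pH)
  act <- species_activities(conc, anchor$ionic_strength_mol_l,
                            anchor$temp_C)
  TK <- anchor$temp_C + 273.15
  dg_sr <- gibbs_energy(rx$SR_acetate, TK,
                        activity_quotient(rx$SR_acetate, act))
  dg_mg <- gibbs_energy(rx$MG_acetate, TK,
                        activity_quotient(rx$MG_acetate, act))
  expect_equal(dg_sr, -105, tolerance = 1e-3)
  expect_equal(dg_mg, -43, tolerance = 1e-3)
})

test_that("energetics profile computes dG per depth and reaction", {
  sp <- data.frame(
    depth_mbsf = rep(c(700, 920), each = 5),
    species = rep(c("SO4-2", "CH3COO-", "HCO3-", "HS-", "CH4"), 2),
    conc_mol_l = rep(c(3e-3, 1e-2, 1e-3, 0, 1e-3), 2))
  e <- energetics_profile(sp)
  expect_true(all(c("SR_acetate", "MG_acetate", "AOM") %in% e$reaction))
  expect_equal(unique(e$temp_C), c(72, 94))
  # acetate-fuelled sulfate reduction is strongly exergonic at depth
  expect_lt(e$dG_kj_mol[e$reaction == "SR_acetate" & e$depth_mbsf == 920], -80)
  expect_error(energetics_profile(sp[, -1]), "lacks column")
})
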