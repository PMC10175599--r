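test_that("influent sampling is truncated, deterministic and mean-faithful", {
  spec0 <- influent_spec("x", nh4 = c(5, 0), no2 = c(3, 0), no3 = c(1, 0))
  expect_equal(sample_influent(spec0),
               c(nh4 = 5, no2 = 3, no3 = 1, cod = 0))
  expect_equal(sample_influent(influent_phase1(), seed = 11),
               sample_influent(influent_phase1(), seed = 11))
  set.seed(3)
  draws <- replicate(10000, sample_influent(influent_phase1())[["nh4"]])
  expect_true(all(draws >= 0))
  expect_lt(abs(mean(draws) - 14.3), 0.1)
  # mean far below zero: nearly every raw draw is negative and truncated
  tiny <- influent_spec("x", nh4 = c(0.01, 0.001), no2 = c(0, 0),
                        no3 = c(0, 0))
  expect_gte(sample_influent(tiny, seed = 1)[["nh4"]], 0)
})

test_that("a biomass-free cycle is pure dilution with zero ground truth", {
  kin0 <- kinetic_params(x_total = 0)
  st <- c(nh4 = 2, no2 = 1, no3 = 4, cod = 0)
  inf <- c(nh4 = 14, no2 = 14, no3 = 1, cod = 10)
  cyc <- simulate_cycle(st, inf, kinetics = kin0)
  expect_equal(cyc$state, 0.5 * inf + 0.5 * st, tolerance = 1e-9)
  expect_true(all(abs(unlist(cyc$truth)) < 1e-12))
})

test_that("an anammox-only cycle reproduces the configured stoichiometric ratios", {
  kin <- kin_guilds(anammox = 0.10)
  cyc <- simulate_cycle(c(nh4 = 0.5, no2 = 0.5, no3 = 1, cod = 0),
                        c(nh4 = 14.3, no2 = 18.9, no3 = 1.2, cod = 0),
                        kinetics = kin, do_mode = do_prescribed(0))
  pr <- cyc$profile
  n <- nrow(pr)
  dnh4 <- pr$nh4_mgN_L[1] - pr$nh4_mgN_L[n]
  dno2 <- pr$no2_mgN_L[1] - pr$no2_mgN_L[n]
  dno3 <- pr$no3_mgN_L[n] - pr$no3_mgN_L[1]
  expect_gt(dnh4, 5)                        # substantial conversion happened
  expect_equal(dno2 / dnh4, 1.32, tolerance = 0.01)
  expect_equal(dno3 / dnh4, 0.26, tolerance = 0.01)
  expect_equal(delta_nitrate_ammonium_ratio(endpoints_from_profile(pr)),
               0.26, tolerance = 0.01)
})

test_that("nitrogen and COD closure hold to integrator tolerance and concentrations stay non-negative", {
  scenarios <- list(
    recovery_cycle(),
    simulate_cycle(c(nh4 = 1, no2 = 1, no3 = 6, cod = 0),
                   c(nh4 = 14.3, no2 = 14.1, no3 = 1.2, cod = 0),
                   kinetics = kinetic_params(),
                   do_mode = do_prescribed(0.07)),
    simulate_cycle(c(nh4 = 0.5, no2 = 0.5, no3 = 1.5, cod = 1),
                   c(nh4 = 12.5, no2 = 12.3, no3 = 2.0, cod = 24.2),
                   kinetics = kinetic_params(),
                   do_mode = do_prescribed(0.03)))
  for (cyc in scenarios) {
    res <- closure_residuals(cyc)
    expect_lt(abs(res[["n_residual_rel"]]), 1e-6)
    expect_lt(abs(res[["cod_residual_rel"]]), 1e-6)
    pr <- cyc$profile
    expect_true(all(pr$nh4_mgN_L >= 0 & pr$no2_mgN_L >= 0 &
                      pr$no3_mgN_L >= 0 & pr$cod_mg_L >= 0))
    expect_true(all(unlist(cyc$truth) >= 0))
  }
})

test_that("endpoint apportionment recovers simulated ground truth (nitrifiers off, closed stoichiometry)", {
  cyc <- recovery_cycle()
  app <- apportion_phase2(endpoints_from_profile(cyc$profile),
                          stoich_params("closed"))
  tr <- cyc$truth
  expect_gt(tr$tn_denitritation, 5)   # every pathway is well expressed
  expect_gt(tr$tn_anammox, 5)
  expect_lt(abs(app$tn_anammox - tr$tn_anammox) / tr$tn_anammox, 0.01)
  expect_lt(abs(app$no3_denitratation - tr$no3_denitratation) /
              tr$no3_denitratation, 0.01)
  expect_lt(abs(app$tn_denitritation - tr$tn_denitritation) /
              tr$tn_denitritation, 0.01)
})

test_that("enabling NOB while assuming a nitrification-free balance biases the split in a known direction", {
  cyc <- simulate_cycle(c(nh4 = 1, no2 = 8, no3 = 3, cod = 5),
                        c(nh4 = 8, no2 = 25, no3 = 5, cod = 60),
                        kinetics = kin_guilds(anammox = 0.10, oho = 0.20,
                                              nob = 0.04),
                        do_mode = do_prescribed(0.07))
  expect_gt(cyc$truth$no3_nob, 0.5)
  app <- apportion_phase2(endpoints_from_profile(cyc$profile),
                          stoich_params("closed"))
  tr <- cyc$truth
  # NOB nitrate production masquerades as missing denitratation
  expect_lt(app$no3_denitratation, tr$no3_denitratation)
})

test_that("phase-1 endpoint balance estimates the NOB integral on a nitrifying cycle", {
  cyc <- simulate_cycle(c(nh4 = 1, no2 = 1, no3 = 6, cod = 0),
                        c(nh4 = 14.3, no2 = 14.1, no3 = 1.2, cod = 0),
                        kinetics = kin_guilds(anammox = 0.10, aob = 0.02,
                                              nob = 0.02),
                        do_mode = do_prescribed(0.07))
  app <- apportion_phase1(endpoints_from_profile(cyc$profile),
                          stoich_params("closed"))
  tr <- cyc$truth
  expect_gt(tr$no3_nob, 1)
  expect_lt(abs(app$no3_nob - tr$no3_nob) / tr$no3_nob, 0.05)
  expect_lt(abs(app$nh4_aob - tr$nh4_aob) / tr$nh4_aob, 0.05)
})

test_that("campaigns are deterministic, carry residuals and respond to the operating regime", {
  c1 <- simulate_campaign(3, influent_phase1(), seed = 5)
  c2 <- simulate_campaign(3, influent_phase1(), seed = 5)
  expect_identical(c1$daily, c2$daily)
  expect_equal(nrow(c1$daily), 3)
  expect_equal(c1$meta$effluent_convention, "last cycle endpoint")

  # zero biomass, one day: effluent is the third successive feed dilution
  c0 <- simulate_campaign(1, influent_spec("x", nh4 = c(10, 0),
                                           no2 = c(0, 0), no3 = c(0, 0)),
                          kinetics = kinetic_params(x_total = 0), seed = 1,
                          initial_state = c(nh4 = 0, no2 = 0, no3 = 0,
                                            cod = 0))
  expect_equal(c0$daily$eff_nh4, 10 * (1 - 0.5^3), tolerance = 1e-9)

  # carbon-dosed low-DO regime ends with less effluent nitrate than the
  # organics-free higher-DO regime at the same seed
  pI <- simulate_campaign(8, influent_phase1(),
                          do_mode = do_prescribed(0.07), seed = 9)
  pII <- simulate_campaign(8, influent_phase2(),
                           do_mode = do_prescribed(0.03), seed = 9)
  expect_lt(mean(pII$daily$eff_no3[4:8]), mean(pI$daily$eff_no3[4:8]))
  expect_gt(mean(pII$daily$removal_pct[4:8]),
            mean(pI$daily$removal_pct[4:8]))
})

test_that("measurement noise is seeded, truncated and scales as specified", {
  p <- batch_profile(time = c(0, 30, 60), nh4 = c(5, 4, 3),
                     no2 = c(2, 1, 0.5), no3 = c(1, 1, 1))
  expect_equal(add_measurement_noise(p, 0, 0), p)
  n1 <- add_measurement_noise(p, 0.2, 0, seed = 4)
  n2 <- add_measurement_noise(p, 0.2, 0, seed = 4)
  expect_identical(n1, n2)
  big <- batch_profile(time = seq_len(1000), nh4 = rep(10, 1000),
                       no2 = rep(10, 1000), no3 = rep(10, 1000))
  noisy <- add_measurement_noise(big, 0.2, 0, seed = 8)
  expect_lt(abs(sd(noisy$nh4_mgN_L) - 0.2) / 0.2, 0.1)
  # hard truncation at zero
  small <- batch_profile(time = 1:200, nh4 = rep(0.01, 200),
                         no2 = rep(0.01, 200), no3 = rep(0.01, 200))
  expect_true(all(add_measurement_noise(small, 1, 0, seed = 2)$nh4_mgN_L >= 0))
})

test_that("simulator input validation", {
  expect_error(simulate_cycle(c(nh4 = -1, no2 = 0, no3 = 0, cod = 0),
                              c(nh4 = 1, no2 = 1, no3 = 1, cod = 0)),
               "negative")
  expect_error(simulate_cycle(c(nh4 = 1), c(nh4 = 1, no2 = 1, no3 = 1,
                                            cod = 0)),
               "must name")
  expect_error(cycle_schedule(react_min = 0), "positive")
  expect_error(kinetic_params(fractions = c(anammox = 2, aob = 0, nob = 0,
                                            oho = 0)),
               "sum")
})

test_that("dynamic DO mode depletes oxygen under heterotrophic load", {
  cyc <- simulate_cycle(c(nh4 = 0.5, no2 = 0.5, no3 = 1.5, cod = 1),
                        c(nh4 = 12.5, no2 = 12.3, no3 = 2.0, cod = 24.2),
                        kinetics = kinetic_params(),
                        do_mode = do_mass_transfer(kla = 0.05, do_sat = 8.2,
                                                   do_init = 0.07))
  expect_true(all(cyc$profile$do_mg_L >= 0))
  # aerobic COD oxidation holds DO well below equilibrium with the gas phase
  expect_lt(cyc$profile$do_mg_L[nrow(cyc$profile)], 1)
  expect_gt(cyc$truth$cod_aerobic, 0)
})
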