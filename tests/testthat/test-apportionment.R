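test_that("mix_feed blends residual and influent at the exchange ratio", {
  expect_equal(unname(mix_feed(c(nh4 = 0), c(nh4 = 14.3), 0.5)), 7.15)
  r <- c(nh4 = 3, no2 = 1)
  i <- c(no2 = 10, nh4 = 12)                 # order-insensitive
  expect_equal(mix_feed(r, i, 1), c(nh4 = 12, no2 = 10))
  expect_equal(mix_feed(r, r, 0.37), r)      # fixed point
  expect_error(mix_feed(c(nh4 = 1), c(no2 = 1), 0.5), "analyte")
  expect_error(mix_feed(r, i[c("nh4", "no2")], 0), "exchange_ratio")
})

test_that("nitrifying-cycle balance assigns TN loss, AOB and NOB shares", {
  # hand evaluation: dN = 29 - 13 = 16, AOB = 12 - 16/2.04,
  # NOB = 8 - 16*0.26/2.04
  ep <- cycle_endpoints(14, 14, 1, 2, 2, 9)
  app <- apportion_phase1(ep)
  expect_equal(app$delta_n, 16)
  expect_equal(app$tn_anammox, 16)
  expect_equal(app$nh4_aob, 12 - 16 / 2.04, tolerance = 1e-12)
  expect_equal(app$nh4_aob, 4.156863, tolerance = 1e-6)
  expect_equal(app$no3_nob, 8 - 16 * 0.26 / 2.04, tolerance = 1e-12)
  expect_equal(app$no3_nob, 5.960784, tolerance = 1e-6)
  expect_length(app$warnings, 0)

  still <- apportion_phase1(cycle_endpoints(5, 5, 2, 5, 5, 2))
  expect_equal(still$tn_anammox, 0)
  expect_equal(still$nh4_aob, 0)
  expect_equal(still$no3_nob, 0)
})

test_that("the 2.04 mass-balance constant leaves a residual on exact-stoichiometry data that closed mode removes", {
  ep <- anammox_endpoints(10)                # NH4 10->0, NO2 13.2->0, NO3 0->2.6
  app <- apportion_phase1(ep)                # paper constants
  expect_equal(app$nh4_aob, 10 - 20.6 / 2.04, tolerance = 1e-9)
  expect_lt(app$nh4_aob, 0)
  expect_match(app$warnings, "nh4_aob", all = FALSE)
  clamped <- apportion_phase1(ep, clamp = TRUE)
  expect_equal(clamped$nh4_aob, 0)
  expect_match(clamped$warnings, "nh4_aob", all = FALSE)

  closed <- stoich_params("closed")
  expect_equal(closed$r_tn_per_nh4, 2.06)
  app_c <- apportion_phase1(ep, closed)
  expect_equal(app_c$nh4_aob, 0, tolerance = 1e-9)
  expect_equal(app_c$no3_nob, 0, tolerance = 1e-9)
  app2_c <- apportion_phase2(ep, closed)
  expect_equal(app2_c$no3_denitratation, 0, tolerance = 1e-9)
  expect_equal(app2_c$tn_denitritation, 0, tolerance = 1e-9)
})

test_that("denitrifying-cycle balance splits TN loss between anammox and denitritation", {
  # hand evaluation: tn_an = 10*2.04, dnra = 2 + 2.6 - 1, dnri = 21 - 20.4
  ep <- cycle_endpoints(10, 10, 2, 0, 0, 1)
  app <- apportion_phase2(ep)
  expect_equal(app$tn_anammox, 20.4)
  expect_equal(app$no3_denitratation, 3.6, tolerance = 1e-12)
  expect_equal(app$delta_n, 21)
  expect_equal(app$tn_denitritation, 0.6, tolerance = 1e-12)
  expect_length(app$warnings, 0)

  # nitrate production beyond the anammox yield violates the
  # no-nitrification assumption and surfaces as negative denitratation
  bad <- apportion_phase2(cycle_endpoints(10, 12, 0, 0, 0, 5))
  expect_equal(bad$no3_denitratation, 0 + 20.4 * 0.26 / 2.04 - 5)
  expect_lt(bad$no3_denitratation, 0)
  expect_match(bad$warnings, "no3_denitratation", all = FALSE)
})

test_that("phase-2 identity and linearity hold over random endpoints", {
  set.seed(42)
  for (i in 1:200) {
    v <- runif(6, 0, 30)
    ep <- cycle_endpoints(v[1], v[2], v[3], v[4], v[5], v[6])
    app <- apportion_phase2(ep)
    expect_identical(app$delta_n - app$tn_anammox - app$tn_denitritation, 0)
    # additivity over a split at an intermediate state
    m <- runif(3, 0, 30)
    ep_a <- cycle_endpoints(v[1], v[2], v[3], m[1], m[2], m[3])
    ep_b <- cycle_endpoints(m[1], m[2], m[3], v[4], v[5], v[6])
    for (fun in list(apportion_phase1, apportion_phase2)) {
      whole <- fun(ep); pa <- fun(ep_a); pb <- fun(ep_b)
      for (f in setdiff(names(whole),
                        c("mode", "params", "clamped", "warnings")))
        expect_equal(whole[[f]], pa[[f]] + pb[[f]], tolerance = 1e-9)
    }
  }
})

test_that("pathway contribution percentages", {
  app <- apportion_phase2(cycle_endpoints(10, 10, 2, 0, 0, 1))
  shares <- pathway_contributions(app)
  expect_equal(unname(shares["anammox"]), 20.4 / 21 * 100, tolerance = 1e-9)
  expect_equal(sum(shares), 100)
  pure <- apportion_phase2(anammox_endpoints(10), stoich_params("closed"))
  expect_equal(unname(pathway_contributions(pure)["anammox"]), 100,
               tolerance = 1e-9)
  # nitrifying cycle: NOB vs anammox share of nitrate production
  app1 <- apportion_phase1(cycle_endpoints(14, 14, 1, 2, 2, 9))
  s1 <- pathway_contributions(app1)
  expect_equal(unname(s1["nitrification"]), 5.960784 / 8 * 100,
               tolerance = 1e-4)
  expect_error(pathway_contributions(
    apportion_phase2(cycle_endpoints(1, 1, 1, 1, 1, 1))), "delta_n")
})

test_that("nitrate-produced-per-ammonium-removed diagnostic", {
  expect_equal(delta_nitrate_ammonium_ratio(anammox_endpoints(10)), 0.26,
               tolerance = 1e-12)
  expect_equal(delta_nitrate_ammonium_ratio(cycle_endpoints(14, 0, 1, 2, 0, 9)),
               8 / 12)
  expect_equal(delta_nitrate_ammonium_ratio(cycle_endpoints(5, 0, 2, 1, 0, 2)),
               0)
  # net nitrate consumption gives a negative ratio
  expect_lt(delta_nitrate_ammonium_ratio(cycle_endpoints(5, 0, 4, 1, 0, 2)), 0)
  expect_error(delta_nitrate_ammonium_ratio(cycle_endpoints(2, 0, 0, 2, 0, 1)),
               "ammonium")
})

test_that("NTR series, maximum and guards", {
  # linear drawdown 15 -> 5 with nitrite rising to 5: endpoint NTR 50 %
  p <- batch_profile(time = c(0, 60, 120, 180, 240),
                     nh4 = rep(0, 5),
                     no2 = c(0, 1.25, 2.5, 3.75, 5),
                     no3 = c(15, 12.5, 10, 7.5, 5))
  r <- nitrate_to_nitrite_transformation(p)
  expect_true(r$defined)
  expect_equal(r$ntr[length(r$ntr)], 50)
  expect_equal(r$max_ntr, 50)
  # complete denitrification: nitrite peaks mid-test, max not at endpoint
  p2 <- batch_profile(time = c(0, 60, 120, 180),
                      nh4 = rep(0, 4),
                      no2 = c(0, 4, 6, 0),
                      no3 = c(15, 10, 5, 5))
  r2 <- nitrate_to_nitrite_transformation(p2)
  expect_equal(r2$max_ntr, 80)
  # no nitrite accumulation -> 0 %
  p3 <- batch_profile(time = c(0, 60), nh4 = c(0, 0), no2 = c(0, 0),
                      no3 = c(15, 10))
  expect_equal(nitrate_to_nitrite_transformation(p3)$max_ntr, 0)
  # nitrate never reduced beyond the guard -> flagged, undefined maximum
  p4 <- batch_profile(time = c(0, 60), nh4 = c(0, 0), no2 = c(0, 0.01),
                      no3 = c(15, 14.95))
  r4 <- nitrate_to_nitrite_transformation(p4)
  expect_false(r4$defined)
  expect_true(is.na(r4$max_ntr))
  # invariant: uniform scaling of all concentrations leaves NTR unchanged
  p5 <- p2
  p5$no2_mgN_L <- p5$no2_mgN_L * 3
  p5$no3_mgN_L <- p5$no3_mgN_L * 3
  r5 <- nitrate_to_nitrite_transformation(p5)
  expect_equal(r5$ntr, r2$ntr)
})

test_that("removal efficiency and per-phase summaries", {
  expect_equal(nitrogen_removal_efficiency(26.8, 26.8), 0)
  expect_equal(nitrogen_removal_efficiency(26.8, 0), 100)
  expect_equal(nitrogen_removal_efficiency(26.8, 3.4), 87.31343,
               tolerance = 1e-6)
  expect_error(nitrogen_removal_efficiency(0, 1), "positive")

  camp <- data.frame(day = 1:4, phase = c("I", "I", "II", "II"),
                     inf_nh4 = c(10, 14, 12, 12))
  s <- phase_summary(camp)
  expect_equal(s$mean[s$phase == "I"], 12)
  expect_equal(s$sd[s$phase == "I"], sqrt(8), tolerance = 1e-9)
  expect_equal(s$sd[s$phase == "II"], 0)
  expect_equal(s$n, c(2L, 2L))
  expect_error(phase_summary(camp[1:2, -2]), "phase")
  expect_error(phase_summary(data.frame(phase = "I", inf_nh4 = 1)),
               "fewer than 2")
})

test_that("influent campaign sampled at stated means is recovered by phase_summary", {
  set.seed(7)
  n <- 60
  camp <- data.frame(
    day = 1:n, phase = "I",
    t(vapply(1:n, function(i) sample_influent(influent_phase1()),
             numeric(4))))
  s <- phase_summary(camp, columns = c("nh4", "no2", "no3"))
  means <- c(14.3, 14.1, 1.2)
  sds <- c(2.5, 2.4, 0.8)
  for (i in 1:3) {
    got <- s$mean[s$analyte == c("nh4", "no2", "no3")[i]]
    # oracle: closed-form mean of the zero-truncated normal (the upward
    # shift only matters for nitrate, whose mean sits 1.5 sd above zero)
    mu <- means[i]; sd <- sds[i]
    etrunc <- mu + sd * dnorm(mu / sd) / pnorm(mu / sd)
    expect_lt(abs(got - etrunc), 3 * sd / sqrt(n))
  }
  expect_lt(abs(s$mean[s$analyte == "nh4"] - 14.3), 2 * 2.5 / sqrt(n))
})
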