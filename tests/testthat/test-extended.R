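ext10 <- extended_params(v_L = 1e-6, K_L = 1e6, eta = 1.4, g = 0.01, h = 0.01)

test_that("ly_production_rate sums over replicative pairs only", {
  # hosts of orders 0..2, phage of orders 0..1
  st <- community_state(r = 350, B = c(2e6, 0, 1e6), P = c(2e6, 0),
                        extended = TRUE)
  expect_equal(ly_production_rate(st, 1e-6), 1e-6 * 2e6 * 2e6)  # only B0*P0
  st2 <- community_state(r = 350, B = c(0, 0, 1e6), P = c(2e6, 0),
                         extended = TRUE)
  expect_identical(ly_production_rate(st2, 1e-6), 0)  # no replicative pair
  st3 <- community_state(r = 350, B = c(2e6, 0, 1e6), P = c(4e6, 0),
                         extended = TRUE)
  expect_equal(ly_production_rate(st3, 1e-6),
               2 * ly_production_rate(st, 1e-6))      # bilinear
  st4 <- community_state(r = 350, B = c(2e6, 3e6, 0), P = c(1e6, 2e6),
                         extended = TRUE)
  expect_equal(ly_production_rate(st4, 1e-6),
               1e-6 * (2e6 * 1e6 + 2e6 * 2e6 + 3e6 * 2e6))
})

test_that("ly_effect saturates at K_L", {
  expect_identical(ly_effect(0, 1e6), 0)
  expect_equal(ly_effect(5e5, 1e6), 0.5)
  expect_identical(ly_effect(1e7, 1e6), 1)
  expect_error(ly_effect(-1, 1e6), "non-negative")
})

test_that("extended_rhs adds kill and persistence terms with cell bookkeeping", {
  p <- model_params(v = 1.4, k = 1, e = 5e-7, delta = 8e-8, beta = 80,
                    lam = 0.4, n_orders = 3L, n_phage = 2L)
  st <- community_state(r = 350, B = c(1e6, 5e5, 2e6), P = c(0, 0),
                        extended = TRUE, LY = 2e6, BP = c(1e4, 0))
  lag <- matrix(0, 3, 2)
  d <- extended_rhs(st, p, ext10, lag)
  # E = 1 above K_L: persistence influx g*B0 = 1e4/h, return h*BP0 = 100/h
  expect_equal(d$dBP[1], 0.01 * 1e6 - 0.01 * 1e4)
  # d(B + BP) has no g/h terms: conversion conserves cells
  psi <- monod_psi(350, 1.4, 1)
  expect_equal(d$dB[1] + d$dBP[1], (psi - 1.4) * 1e6 + 0)
  # eta applies to every dividing order, including the two-spacer BIM
  expect_equal(d$dB[3], (psi - 1.4) * 2e6)
  # near-zero net growth at full effect: psi(350) - eta ~ -0.004/h
  expect_equal(psi - 1.4, -1.4 / 351)
  # no phage, no LY production
  expect_identical(d$dLY, 0)
})

test_that("the extension reduces exactly to the basic model when silent", {
  p <- model_params(v = 1.4, k = 1, e = 5e-7, delta = 8e-8, beta = 80,
                    lam = 0.4, m = 1e-6, mu = 1e-6, n_orders = 3L,
                    n_phage = 2L)
  ctl <- sim_control(dt = 1e-3, duration = 6, seed = 42,
                     event_mode = "poisson")
  basic <- run_scenario(scenario(
    params = p, control = ctl,
    init = community_state(r = 350, B = c(2e6, 0, 2e6), P = c(2e6, 0)),
    name = "basic"))
  silent_ext <- run_scenario(scenario(
    params = p, control = ctl,
    ext = extended_params(v_L = 0, K_L = 1e6, eta = 1.4, g = 0.01, h = 0.01),
    init = community_state(r = 350, B = c(2e6, 0, 2e6), P = c(2e6, 0),
                           extended = TRUE),
    name = "ext-silent"))
  shared <- setdiff(names(basic), c("LY", "BP0", "BP1"))
  expect_identical(bare_df(basic), bare_df(silent_ext)[shared])
  expect_identical(ts_events(basic), ts_events(silent_ext))
  expect_true(all(silent_ext$LY == 0))
  expect_true(all(silent_ext$BP0 == 0))
})

test_that("LY never decreases within a transfer and drops only by dilution", {
  ts <- run_cached("fig10bcd", run_scenario(preset_scenario("fig10bcd",
                                                            seed = 1)))
  d <- as.data.frame(ts)
  cyc <- floor((d$time_h - 1e-6) / 24)   # growth-cycle index per sample
  same <- diff(cyc) == 0
  expect_true(all(diff(d$LY)[same] >= -1e-9 * max(d$LY)))
  # across each transfer boundary the 100-fold dilution dominates
  bnd <- which(!same)
  bnd <- bnd[bnd > 1 & d$LY[bnd] > 0]
  expect_true(all(d$LY[bnd + 1] < d$LY[bnd] / 50))
})

test_that("persisters and LY stay non-negative and persister conversion is bounded", {
  ts <- run_cached("fig10bcd", run_scenario(preset_scenario("fig10bcd",
                                                            seed = 1)))
  d <- as.data.frame(ts)
  expect_true(all(d$LY >= 0))
  expect_true(all(d$BP0 >= 0) && all(d$BP1 >= 0))
})
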