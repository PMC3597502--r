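test_that("event probabilities follow the lagged-flux product formulas", {
  expect_identical(bim_event_probability(0, 1e9, 1), 0)
  expect_equal(bim_event_probability(1e-6, 3.2e5, 1e-3), 3.2e-4)
  expect_error(bim_event_probability(1e-6, 3.2e5, 10), "poisson")
  expect_equal(bim_event_probability(1e-6, 3.2e5, 10, mode = "poisson"), 3.2)
  expect_identical(cem_event_probability(0, 1e9, 80, 1), 0)
  expect_equal(cem_event_probability(1e-6, 1e5, 80, 1e-3), 7.9e-3)
  # volume scales the expectation (individuals, not densities)
  expect_equal(cem_event_probability(1e-6, 1e5, 80, 1e-3, volume = 2),
               2 * 7.9e-3)
})

test_that("draw_events matches the binomial oracle and rejects bad input", {
  expect_error(draw_events(c(0.5, NA)), "malformed")
  expect_error(draw_events(1.2, "unit"), "< 1")
  set.seed(11)
  n <- 1e5
  hits <- sum(draw_events(rep(0.01, n), "unit"))
  sigma <- sqrt(n * 0.01 * 0.99)
  expect_lt(abs(hits - n * 0.01), 3 * sigma)
  pois <- sum(draw_events(rep(0.01, n), "poisson"))
  expect_lt(abs(pois - n * 0.01), 3 * sqrt(n * 0.01))
})

test_that("runs are deterministic in (scenario, seed) and seed-free without channels", {
  sc <- preset_scenario("figS3b", seed = 5)
  a <- run_scenario(sc)
  b <- run_scenario(sc)
  expect_identical(bare_df(a), bare_df(b))
  expect_identical(ts_events(a), ts_events(b))
  c2 <- run_scenario(preset_scenario("figS3b", seed = 6))
  expect_false(identical(bare_df(a), bare_df(c2)))
  # m = mu = 0: no stochastic channels, any seed gives identical output
  d1 <- run_scenario(preset_scenario("fig2", seed = 1))
  d2 <- run_scenario(preset_scenario("fig2", seed = 99))
  expect_identical(bare_df(d1), bare_df(d2))
  expect_equal(nrow(ts_events(d1)), 0L)
})

test_that("halving dt converges at first order", {
  res <- lapply(c(4e-3, 2e-3, 1e-3), function(dt) {
    sc <- scenario(
      params = ref_params1(),
      init = community_state(r = 350, B = 2e6, P = 2e4),
      control = sim_control(dt = dt, duration = 24, output_every = 1),
      name = "dt-check")
    ts <- run_scenario(sc)
    c(P = ts$P0[nrow(ts)], r = ts$r_ug_ml[nrow(ts)])
  })
  d1 <- abs(res[[1]] - res[[2]])
  d2 <- abs(res[[2]] - res[[3]])
  expect_true(all(d2 < 2 * d1))
  expect_true(all(d1 > 0))
})

test_that("expected event counts match the analytic per-step sums", {
  # deterministic trajectory (events barely perturb it): expected CEM
  # creations = mu * (beta - 1) * integral of the lagged flux
  mk <- function(mu, seed) scenario(
    params = model_params(v = 1.4, k = 1, e = 5e-7, delta = 8e-8, beta = 80,
                          lam = 0.4, mu = mu, n_orders = 1L, n_phage = 2L),
    init = community_state(r = 350, B = 1e7, P = c(1e6, 0)),
    control = sim_control(dt = 1e-3, duration = 1.4, output_every = 0.01,
                          seed = seed, event_mode = "poisson"),
    name = "events")
  base <- run_scenario(mk(0, NULL))
  # cumulative bursts = integral(flux) - standing cohort; trapezoidal rule
  fl <- 8e-8 * base$B0 * base$P0
  tt <- base$time_h
  bursts <- sum(diff(tt) * (utils::head(fl, -1) + utils::tail(fl, -1)) / 2) -
    base$M_0_0[nrow(base)]
  mu <- 4e-7
  expected <- mu * 79 * bursts
  counts <- vapply(1:100, function(s) sum(ts_events(run_scenario(mk(mu, s)))$count),
                   numeric(1))
  expect_lt(abs(mean(counts) - expected),
            3 * sqrt(expected / 100) + 0.03 * expected)
  expect_gt(expected, 5)   # the check has power
})

test_that("unit and poisson modes agree in distribution at small expectations", {
  mk <- function(mode, seed) scenario(
    params = model_params(v = 1.4, k = 1, e = 5e-7, delta = 8e-8, beta = 80,
                          lam = 0.4, mu = 5e-8, n_orders = 1L, n_phage = 2L),
    init = community_state(r = 350, B = 1e7, P = c(1e6, 0)),
    control = sim_control(dt = 1e-3, duration = 1.4, seed = seed,
                          event_mode = mode, output_every = 0.7),
    name = "modes")
  nu <- vapply(1:100, function(s) nrow(ts_events(run_scenario(mk("unit", s)))),
               numeric(1))
  np <- vapply(1:100, function(s) sum(ts_events(run_scenario(mk("poisson", s)))$count),
               numeric(1))
  se <- sqrt(stats::var(nu) / 100 + stats::var(np) / 100)
  expect_lt(abs(mean(nu) - mean(np)), 4 * se + 0.5)
  expect_gt(mean(np), 0.5)
})

test_that("unit mode aborts when a per-step probability reaches 1", {
  sc <- scenario(
    params = model_params(v = 1.4, k = 1, e = 5e-7, delta = 8e-8, beta = 80,
                          lam = 0.4, mu = 1e-3, n_orders = 1L, n_phage = 2L),
    init = community_state(r = 350, B = 1e8, P = c(1e7, 0)),
    control = sim_control(dt = 1e-3, duration = 2, seed = 1,
                          event_mode = "unit"),
    name = "cap")
  expect_error(run_scenario(sc), "poisson")
})

test_that("serial transfer dilutes, replenishes, and is the identity at 1x", {
  st <- community_state(r = 0.3, B = c(5e8, 1e6), P = c(2e9, 0),
                        M = matrix(c(1e4, 0, 2e4, 3e4), 2, 2))
  out <- serial_transfer(st, transfer_schedule(dilution = 100, R = 350))
  expect_equal(out$state$B, c(5e6, 1e4))
  expect_equal(out$state$P, c(2e7, 0))
  expect_equal(out$state$M, st$M / 100)
  expect_equal(out$state$r, 350)
  idem <- serial_transfer(st, transfer_schedule(dilution = 1, R = 0.3))
  expect_equal(idem$state, st)
  # buffer entries are diluted with the cells they represent
  buf <- delay_buffer(0.4, 1e-3, 2, 2, M0 = matrix(c(1e4, 0, 2e4, 3e4), 2, 2))
  out <- serial_transfer(st, transfer_schedule(dilution = 100, R = 350), buf)
  expect_equal(out$buffer$mat, buf$mat / 100)
})

test_that("stochastic rounding gives binomial survival of small populations", {
  st <- community_state(r = 0, B = 50, P = 0)
  sch <- transfer_schedule(dilution = 100, R = 350, stochastic_rounding = TRUE)
  set.seed(21)
  survived <- vapply(1:2000, function(i) {
    serial_transfer(st, sch)$state$B >= 1
  }, logical(1))
  p_true <- 1 - 0.99^50                    # ~ 0.395
  expect_lt(abs(mean(survived) - p_true), 3 * sqrt(p_true * (1 - p_true) / 2000))
  # large populations stay deterministic
  stL <- community_state(r = 0, B = 5e8, P = 0)
  expect_equal(serial_transfer(stL, sch)$state$B, 5e6)
})

test_that("sim_step advances one hybrid step with exact M bookkeeping", {
  p <- ref_params1()
  eng <- sim_engine(community_state(r = 350, B = 2e6, P = 2e6), p,
                    control = sim_control(dt = 1e-3, duration = 1))
  eng <- sim_step(eng, 500L)
  expect_equal(eng$state$t, 0.5)
  # M equals the delay-buffer integral at all times
  expect_equal(eng$state$M[1, 1],
               sum(eng$env$bufmat) * 1e-3, tolerance = 1e-9)
  expect_true(eng$state$M[1, 1] > 0)
})
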