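test_that("monod_psi matches its definition and bounds", {
  expect_identical(monod_psi(0, 1.4, 1), 0)
  expect_equal(monod_psi(1, 1.4, 1), 0.7)          # half-maximum at r = k
  expect_equal(monod_psi(350, 1.4, 1), 1.4 * 350 / 351)
  r <- seq(0, 1000, length.out = 200)
  psi <- monod_psi(r, 1.4, 1)
  expect_true(all(diff(psi) >= 0))                 # monotone in r
  expect_true(all(psi <= 1.4))
  expect_error(monod_psi(-1, 1.4, 1), "non-negative")
})

test_that("infection_flux is bilinear mass action", {
  expect_identical(infection_flux(0, 1e6, 8e-8), 0)
  expect_equal(infection_flux(2e6, 2e6, 8e-8), 3.2e5)
  expect_equal(infection_flux(4e6, 2e6, 8e-8), 6.4e5)
  expect_equal(infection_flux(2e6, 4e6, 8e-8), 6.4e5)
  expect_error(infection_flux(-1, 1, 1), "non-negative")
})

test_that("burst_release applies the (1-m)(beta-1) rule", {
  expect_equal(burst_release(1e5, 0, 80), 7.9e6)
  expect_identical(burst_release(1e5, 1, 80), 0)   # all infections form BIMs
  expect_identical(burst_release(0, 1e-6, 80), 0)
  expect_error(burst_release(-1, 0, 80), "non-negative")
})

test_that("basic_rhs implements the flux rules of the three-order model", {
  p <- ref_params1()
  p3 <- model_params(v = p$v, k = p$k, e = p$e, delta = p$delta,
                     beta = p$beta, lam = p$lam, n_orders = 3L)
  zero_lag <- matrix(0, 3, 3)

  # phage-free limit: pure Monod growth
  st <- community_state(r = 350, B = c(1e6, 2e6, 3e6), P = c(0, 0, 0))
  d <- basic_rhs(st, p3, zero_lag)
  psi <- monod_psi(350, p$v, p$k)
  expect_equal(d$dB, psi * st$B)
  expect_equal(d$dr, -p$e * psi * sum(st$B))
  expect_equal(d$dP, c(0, 0, 0))

  # phage adsorbing to an immune host are lost; the host keeps growing
  st <- community_state(r = 350, B = c(0, 0, 1e6), P = c(1e6, 0, 0))
  d <- basic_rhs(st, p3, zero_lag)
  expect_equal(d$dP[1], -p$delta * 1e6 * 1e6)
  expect_equal(d$dB[3], psi * 1e6)
  expect_equal(d$dM, matrix(0, 3, 3))     # no replicative pair -> no cohort

  # replicative infection builds the cohort and burst feeds the phage
  st <- community_state(r = 350, B = c(1e6, 0, 0), P = c(0, 2e6, 0))
  lag <- matrix(0, 3, 3); lag[1, 2] <- 1e4
  d <- basic_rhs(st, p3, lag)
  expect_equal(d$dM[1, 2], p$delta * 1e6 * 2e6 - 1e4)
  expect_equal(d$dP[2],
               -p$delta * 2e6 * 1e6 + (p$beta - 1) * 1e4)
  expect_error(basic_rhs(st, p, zero_lag), "dimensions")
})

test_that("phage-free runs conserve r + e * sum(B) and match the closed form", {
  sc <- scenario(
    params = ref_params1(),
    init = community_state(r = 350, B = 2e6, P = 0),
    control = sim_control(dt = 1e-3, duration = 24),
    name = "phage-free")
  ts <- run_scenario(sc)
  inv <- ts$r_ug_ml + 5e-7 * ts$B0
  # Euler preserves this linear invariant exactly until the resource-zero clip
  pre <- ts$time_h < 4
  expect_lt(max(abs(inv[pre] - inv[1])) / inv[1], 1e-12)
  expect_lt(max(abs(inv - inv[1])) / inv[1], 1e-3)
  # r(0) - r(t) = e (B(t) - B(0)) at every output time
  expect_equal(350 - ts$r_ug_ml[pre], 5e-7 * (ts$B0[pre] - 2e6),
               tolerance = 1e-10)
  # resource exhaustion: B(24 h) ~ B(0) + R / e
  expect_equal(ts$B0[nrow(ts)], 2e6 + 350 / 5e-7, tolerance = 0.01)
})

test_that("phage decline is monotone when no replicative host exists", {
  p <- model_params(v = 1.4, k = 1, e = 5e-7, delta = 8e-8, beta = 80,
                    lam = 0.4, n_orders = 2L)
  sc <- scenario(
    params = p,
    init = community_state(r = 350, B = c(0, 2e6), P = c(2e6, 0)),
    control = sim_control(dt = 1e-3, duration = 8),
    name = "no-host")
  ts <- run_scenario(sc)
  expect_true(all(diff(ts$P0) <= 0))
  expect_true(all(as.matrix(ts[-1]) >= 0))   # non-negativity under clipping
})

test_that("delay buffer enforces the lam/dt contract and M bookkeeping", {
  expect_error(delay_buffer(0.4, 0.003, 1), "integer multiple")
  buf <- delay_buffer(0.4, 1e-3, 2, 2)
  expect_equal(ncol(buf$mat), 400L)
  expect_equal(nrow(buf$mat), 3L)            # pairs (0,0) (0,1) (1,1)
  M0 <- matrix(c(10, 0, 20, 40), 2, 2)       # column-major: M[2,1]=0 non-rep
  buf <- delay_buffer(0.4, 1e-3, 2, 2, M0 = M0)
  expect_equal(buffer_cohorts(buf), M0)      # sum * dt reproduces M
})

test_that("replicative pairs enumerate j >= i in fixed ascending order", {
  pr <- replicative_pairs(3, 2)
  expect_equal(pr$i, c(0L, 0L, 1L))
  expect_equal(pr$j, c(0L, 1L, 1L))
  expect_true(all(pr$j >= pr$i))
  pr <- replicative_pairs(1, 2)              # phage orders may exceed hosts
  expect_equal(nrow(pr), 2L)
})

test_that("engine trajectories match the independent delay integrator", {
  p <- ref_params1()
  dt <- 1e-4
  ts <- run_cached("oracle_engine", run_scenario(scenario(
    params = p,
    init = community_state(r = 350, B = 2e6, P = 2e6),
    control = sim_control(dt = dt, duration = 12, output_every = 0.5),
    name = "oracle-check")))
  ref <- run_cached("oracle_ref",
                    ref_basic_sim(p$v, p$k, p$e, p$delta, p$beta, p$lam,
                                  r0 = 350, B0 = 2e6, P0 = 2e6,
                                  dt = dt, t_end = 12, sample_every = 0.5))
  expect_equal(nrow(ts), nrow(ref))
  for (col in c("r", "B", "P")) {
    ours <- switch(col, r = ts$r_ug_ml, B = ts$B0, P = ts$P0)
    sel <- ref[[col]] >= 1        # compare where at least one individual/ml
    expect_true(any(sel))
    expect_lt(max(abs(ours[sel] - ref[[col]][sel]) / ref[[col]][sel]), 0.01)
  }
})
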