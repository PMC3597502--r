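#' Synthetic growth curve (phage-free trajectory plus measurement noise)
#'
#' Simulates a phage-free batch culture under the basic model, converts the
#' cell densities to OD (linearly, or through an [od_calibration()]), and
#' multiplies each reading by lognormal noise `exp(N(0, sd^2))`.  The
#' generating parameters are attached as attributes so recovery can be
#' asserted against them.
#'
#' @param v Maximum growth rate (per hour).
#' @param noise_sd Standard deviation of the log-readings (0 = noise-free).
#' @param seed RNG seed (`NULL` leaves the RNG state alone).
#' @param times Uniform sampling grid (hours), starting at 0.
#' @param k,e Monod constant and conversion efficiency.
#' @param R Initial resource concentration (ug/ml).
#' @param B0 Initial density (cells/ml).
#' @param od_per_cell Linear density-to-OD factor (ignored when
#'   `calibration` is given).
#' @param calibration Optional [od_calibration()] used for the conversion.
#' @param dt Euler step (hours); the grid spacing must be a multiple of it.
#' @return A [growth_curve()] (kind `"od"`) with attributes `v`, `noise_sd`,
#'   `seed`.
#' @export
synth_growth_curve <- function(v = 1.37, noise_sd = 0, seed = NULL,
                               times = seq(0, 2, by = 0.25),
                               k = 1, e = 5e-7, R = 350, B0 = 2e6,
                               od_per_cell = 1e-9, calibration = NULL,
                               dt = 1e-3) {
  if (v <= 0) stop("'v' must be positive")
  if (times[1] != 0 || length(unique(round(diff(times), 12))) != 1L)
    stop("'times' must be a uniform grid starting at 0")
  sc <- scenario(
    params = model_params(v = v, k = k, e = e, delta = 0, beta = 80,
                          lam = 0.4, n_orders = 1L),
    init = community_state(r = R, B = B0, P = 0),
    control = sim_control(dt = dt, duration = max(times), seed = NULL,
                          output_every = diff(times)[1]),
    name = "synth-growth", note = "phage-free fixture")
  ts <- run_scenario(sc)
  dens <- ts$B0[match(round(times, 9), round(ts$time_h, 9))]
  if (anyNA(dens)) stop("sampling grid not aligned with dt")
  od <- if (is.null(calibration)) dens * od_per_cell
        else density_to_od(calibration, dens)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    od <- od * exp(stats::rnorm(length(od), 0, noise_sd))
  }
  out <- growth_curve(times, od, kind = "od")
  attr(out, "v") <- v
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  out
}

#' Synthetic one-step growth experiment
#'
#' Simulates the one-step protocol in the basic model: a high-density
#' adsorption phase (2e8 cells/ml with 1e6 phage/ml for 15 min by default),
#' then a large dilution that effectively stops further adsorption, with the
#' plaque-forming density `PFU(t) = free phage + infected centers` sampled on
#' the design grid.  Each infected cohort carries its own infection time
#' through the delay buffer, so bursts appear one latent period after each
#' cohort's adsorption.  PFU values are reported on the scale of the
#' original (undiluted) mixture.  Optional counting noise draws Poisson
#' plaque counts at a stated plating dilution.
#'
#' @param params [model_params()] (single host order suffices).
#' @param design [one_step_design()].
#' @param noise_plating Plating dilution for Poisson counting noise, or
#'   `NULL` (default) for noise-free output.
#' @param seed RNG seed for the counting noise.
#' @param B0,P0 Densities in the adsorption mixture (cells/ml, phage/ml).
#' @param adsorb_time Length of the adsorption phase (hours).
#' @param dilution Fold-dilution after the adsorption phase.
#' @param R Resource concentration (ug/ml).
#' @return A data.frame `time_h, pfu` with attributes `params`, `design`,
#'   `seed`.
#' @export
synth_one_step <- function(params = NULL, design = one_step_design(),
                           noise_plating = NULL, seed = NULL,
                           B0 = 2e8, P0 = 1e6, adsorb_time = 0.25,
                           dilution = 1e4, R = 350) {
  if (is.null(params))
    params <- model_params(v = 1.4, k = 1, e = 5e-7, delta = 8e-8,
                           beta = 80, lam = 0.4, n_orders = 1L)
  dt <- 1 / 1200
  grid <- design$times
  spacing <- diff(grid)[1]
  os <- as.integer(round(spacing / dt))
  control <- sim_control(dt = dt, duration = max(grid), seed = NULL,
                         output_every = spacing)
  init <- community_state(r = R, B = B0, P = P0)
  env <- .engine_init(init, params, NULL, control)
  n1 <- as.integer(round(adsorb_time / dt))
  n2 <- as.integer(round(max(grid) / dt)) - n1
  # sample columns: t, r, B.., P.., M..
  np <- params$n_phage
  nrep <- env$geom$nrep
  pcols <- 2L + params$n_orders + seq_len(np)
  mcols <- 2L + params$n_orders + np + seq_len(nrep)
  env <- .engine_run(env, params, NULL, control, n1, os)
  s1 <- env$samples
  sched <- transfer_schedule(period = 24, dilution = dilution, R = R,
                             n_transfers = 1, stochastic_rounding = FALSE)
  env <- .engine_transfer(env, sched, control$volume)
  env <- .engine_run(env, params, NULL, control, n2, os)
  s2 <- env$samples
  pfu1 <- rowSums(s1[, c(pcols, mcols), drop = FALSE])
  pfu2 <- rowSums(s2[, c(pcols, mcols), drop = FALSE]) * dilution
  times <- c(0, s1[, 1L], s2[, 1L])
  pfu <- c(sum(init$P), pfu1, pfu2)
  keep <- match(round(grid, 9), round(times, 9))
  if (anyNA(keep)) stop("design grid not aligned with the simulation")
  pfu <- pfu[keep]
  if (!is.null(noise_plating)) {
    if (!is.null(seed)) set.seed(seed)
    counts <- stats::rpois(length(pfu), pfu / noise_plating)
    pfu <- counts * noise_plating
  }
  structure(data.frame(time_h = grid, pfu = pfu),
            params = params, design = design, seed = seed,
            class = c("one_step_data", "data.frame"))
}

#' Synthetic single-plaque lysate with escape-mutant accounting
#'
#' Runs the basic model on a wild-type host to lysis completion (24 h by
#' default) with CEM mutation active, and returns the genotype-resolved
#' final phage densities and the escape-mutant frequency
#' `P1 / (P0 + P1)`.  Uses the Poisson event mode: late in the run the
#' per-step expected number of mutants produced exceeds one.
#'
#' @param mu Per-particle CEM mutation probability.
#' @param B0_init,P0_init Initial host and phage densities (per ml).
#' @param seed RNG seed.
#' @param duration Run length (hours).
#' @param dt Euler step (hours).
#' @return List with `P0`, `P1`, `frequency`, and the full trajectory `ts`.
#' @export
synth_lysate <- function(mu = 1e-6, B0_init = 2e6, P0_init = 1e3,
                         seed = NULL, duration = 24, dt = 1e-3) {
  sc <- scenario(
    params = model_params(v = 1.4, k = 1, e = 5e-7, delta = 8e-8, beta = 80,
                          lam = 0.4, m = 0, mu = mu,
                          n_orders = 1L, n_phage = 2L),
    init = community_state(r = 350, B = B0_init, P = c(P0_init, 0)),
    control = sim_control(dt = dt, duration = duration, seed = seed,
                          event_mode = "poisson", output_every = 0.5),
    name = "synth-lysate", note = "WT lysate fixture with CEM mutation")
  ts <- run_scenario(sc)
  fin <- ts_final_state(ts)
  tot <- fin$P[1] + fin$P[2]
  list(P0 = fin$P[1], P1 = fin$P[2],
       frequency = if (tot > 0) fin$P[2] / tot else 0,
       ts = ts)
}
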