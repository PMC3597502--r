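#' Simulation control settings
#'
#' @param dt Euler step size (hours).  The latent period must be an integer
#'   multiple of `dt`.
#' @param duration Total simulated time (hours); ignored when a transfer
#'   schedule is supplied (then `period * n_transfers` governs).
#' @param seed RNG seed (integer) or `NULL` to leave the RNG state alone.
#' @param volume Culture volume (ml).  Discrete Monte Carlo events change
#'   densities in increments of one individual per volume (`1/volume` per ml).
#' @param event_mode `"unit"` (at most one creation event per channel per
#'   step; per-step probabilities must stay below 1) or `"poisson"`
#'   (Poisson-distributed event counts with the same expectations; needed
#'   when fluxes make per-step expectations exceed 1).
#' @param output_every Sampling interval for the trajectory (hours); must be
#'   an integer multiple of `dt`.
#'
#' @return An object of class `sim_control`.
#' @export
sim_control <- function(dt = 1e-3, duration = 24, seed = NULL, volume = 1,
                        event_mode = c("unit", "poisson"),
                        output_every = 0.1) {
  event_mode <- match.arg(event_mode)
  if (dt <= 0) stop("'dt' must be positive")
  if (duration <= 0) stop("'duration' must be positive")
  if (volume <= 0) stop("'volume' must be positive")
  os <- output_every / dt
  if (abs(os - round(os)) > 1e-8 * max(1, os))
    stop("'output_every' must be an integer multiple of 'dt'")
  structure(list(dt = dt, duration = duration,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 volume = volume, event_mode = event_mode,
                 output_every = output_every),
            class = "sim_control")
}

#' Serial-transfer schedule
#'
#' Daily (by default) passage of a batch culture: at the end of each period
#' all biological state is diluted and the resource is replenished to the
#' fresh concentration `R`.
#'
#' @param period Hours between transfers (default 24).
#' @param dilution Dilution factor (default 100, i.e. 40 ul into 4 ml).
#' @param R Fresh resource concentration at the start of each transfer
#'   (ug/ml, default 350).
#' @param n_transfers Number of growth cycles to simulate.
#' @param stochastic_rounding If `TRUE`, populations whose expected diluted
#'   count (`density * volume / dilution`) falls below 10 individuals are
#'   resampled from a binomial with retention probability `1/dilution`,
#'   allowing true extinction by dilution.
#' @return An object of class `transfer_schedule`.
#' @export
transfer_schedule <- function(period = 24, dilution = 100, R = 350,
                              n_transfers = 2, stochastic_rounding = FALSE) {
  if (period <= 0) stop("'period' must be positive")
  if (dilution < 1) stop("'dilution' must be >= 1")
  if (R < 0) stop("'R' must be non-negative")
  if (n_transfers < 1) stop("'n_transfers' must be >= 1")
  structure(list(period = period, dilution = dilution, R = R,
                 n_transfers = as.integer(n_transfers),
                 stochastic_rounding = isTRUE(stochastic_rounding)),
            class = "transfer_schedule")
}

#' Per-step probability of a BIM-creation event
#'
#' Probability that, during one step of width `dt`, a single BIM of the next
#' order is created from the cohort bursting now: `m * flux * volume * dt`,
#' where `flux` is the lagged replicative infection flux (cells/ml/hr).  The
#' expectation over a run is therefore `m` times the number of bursting
#' infections, as it should be.
#'
#' @param m Spacer-acquisition probability.
#' @param lagged_flux Lagged infection flux (cells/ml/hr).
#' @param dt Step width (hours).
#' @param volume Culture volume (ml).
#' @param mode `"unit"` (errors when the product reaches 1, instructing a
#'   smaller step or `"poisson"` mode) or `"poisson"` (returns the raw
#'   expectation).
#' @return Probability (unit mode) or expectation (poisson mode).
#' @export
bim_event_probability <- function(m, lagged_flux, dt, volume = 1,
                                  mode = c("unit", "poisson")) {
  mode <- match.arg(mode)
  if (any(m < 0) || any(lagged_flux < 0) || any(dt < 0) || any(volume < 0))
    stop("inputs must be non-negative")
  p <- m * lagged_flux * volume * dt
  if (mode == "unit" && any(p >= 1))
    stop("per-step BIM event probability reached 1; ",
         "reduce dt or use event_mode = \"poisson\"")
  p
}

#' Per-step probability of a CEM-creation event
#'
#' As [bim_event_probability()], with the extra factor `beta - 1`: each
#' bursting infection yields `beta - 1` particles, each a CEM with
#' probability `mu`, so `p = mu * flux * (beta - 1) * volume * dt`.
#'
#' @inheritParams bim_event_probability
#' @param mu Per-particle CEM mutation probability.
#' @param beta Burst size.
#' @export
cem_event_probability <- function(mu, lagged_flux, beta, dt, volume = 1,
                                  mode = c("unit", "poisson")) {
  mode <- match.arg(mode)
  if (any(mu < 0) || any(lagged_flux < 0) || any(dt < 0) || any(volume < 0))
    stop("inputs must be non-negative")
  p <- mu * lagged_flux * (beta - 1) * volume * dt
  if (mode == "unit" && any(p >= 1))
    stop("per-step CEM event probability reached 1; ",
         "reduce dt or use event_mode = \"poisson\"")
  p
}

#' Draw Monte Carlo creation events
#'
#' Draws the per-channel event counts for one step from R's global RNG.  In
#' `"unit"` mode each channel gets one uniform draw and yields at most one
#' event (probabilities must be in \[0, 1)); in `"poisson"` mode each channel
#' yields a Poisson count with the given expectation.  The engine applies
#' each count as `count / volume` density added to the destination (and, for
#' CEM events, removed from the source phage, floored at zero).  Channels
#' are always drawn in a fixed order (BIM channels by ascending order, then
#' CEM channels), which is part of the seed-reproducibility contract.
#'
#' @param probabilities Per-channel probabilities (unit mode) or
#'   expectations (poisson mode).
#' @param mode `"unit"` or `"poisson"`.
#' @return Integer vector of event counts, one per channel.
#' @export
draw_events <- function(probabilities, mode = c("unit", "poisson")) {
  mode <- match.arg(mode)
  if (any(!is.finite(probabilities)) || any(probabilities < 0))
    stop("malformed event probabilities")
  if (mode == "unit") {
    if (any(probabilities >= 1))
      stop("unit-mode event probability must be < 1")
    as.integer(stats::runif(length(probabilities)) < probabilities)
  } else {
    stats::rpois(length(probabilities), probabilities)
  }
}

# Internal engine state: a plain list carrying everything the stepper needs.
# Fields: t, r, B, P, Mp (per-pair infected cohorts), LY, BP, bufmat, ptr,
# plus immutable precomputed geometry.
.engine_geometry <- function(params, ext) {
  nb <- params$n_orders
  np <- params$n_phage
  pr <- replicative_pairs(nb, np)
  pih <- pr$i + 1L                      # 1-based host index per pair
  pjp <- pr$j + 1L                      # 1-based phage index per pair
  nrep <- nrow(pr)
  repmat <- outer(seq_len(nb) - 1L, seq_len(np) - 1L, "<=") * 1
  agg <- matrix(0, np, nrep)            # pair fluxes -> per-phage production
  agg[cbind(pjp, seq_len(nrep))] <- 1
  bsel <- which(pih <= nb - 1L)         # BIM channels: host order + 1 exists
  csel <- which(pjp <= np - 1L)         # CEM channels: phage order + 1 exists
  list(nb = nb, np = np, pih = pih, pjp = pjp, nrep = nrep,
       repmat = repmat, agg = agg,
       bsel = bsel, bdest = pih[bsel] + 1L, bfrom = pih[bsel] - 1L,
       csel = csel, cdest = pjp[csel] + 1L, cfrom = pjp[csel] - 1L,
       npers = min(nb, 2L), extended = !is.null(ext))
}

# Advance the engine n_steps steps.  Returns updated scalar state, samples
# taken at multiples of out_steps (counted from step_offset + 1), and events.
# This is the single code path used by sim_step() and run_scenario().
.engine_run <- function(env, params, ext, control, n_steps,
                        out_steps = Inf, t0 = env$t) {
  g <- env$geom
  dt <- control$dt
  V <- control$volume
  dtV <- dt * V
  unit_mode <- control$event_mode == "unit"
  v <- params$v; k <- params$k; e <- params$e; delta <- params$delta
  beta <- params$beta; m <- params$m; mu <- params$mu
  bm1 <- beta - 1
  om_bm1 <- (1 - m) * bm1
  do_bim <- m > 0 && length(g$bsel) > 0L
  do_cem <- mu > 0 && length(g$csel) > 0L
  r <- env$r; B <- env$B; P <- env$P; Mp <- env$Mp
  LY <- env$LY; BP <- env$BP
  bufmat <- env$bufmat; ptr <- env$ptr
  L <- ncol(bufmat)
  pih <- g$pih; pjp <- g$pjp
  repmat <- g$repmat; agg <- g$agg
  ipers <- seq_len(g$npers)
  extd <- g$extended
  if (extd) { v_L <- ext$v_L; K_L <- ext$K_L; eta <- ext$eta
              gg <- ext$g; hh <- ext$h }
  clips <- env$clips
  # sample storage
  n_samp <- if (is.finite(out_steps)) n_steps %/% out_steps else 0L
  samp <- if (n_samp > 0L)
    matrix(NA_real_, n_samp,
           2L + g$nb + g$np + g$nrep + if (extd) 1L + g$npers else 0L)
  isamp <- 0L
  ev <- env$ev; nev <- env$nev

  for (s in seq_len(n_steps)) {
    lag <- bufmat[, ptr]
    psi <- v * r / (r + k)
    rp <- as.vector(repmat %*% P)
    fluxp <- delta * B[pih] * P[pjp]
    sB <- sum(B)
    if (!is.finite(sB) || !is.finite(r))
      stop(sprintf("non-finite state at t = %g h; aborting", t0 + (s - 1) * dt))
    dB <- psi * B - delta * B * rp
    dP <- -delta * P * sB + om_bm1 * as.vector(agg %*% lag)
    dr <- -e * psi * sB
    if (extd) {
      Eeff <- LY / K_L
      if (Eeff > 1) Eeff <- 1
      dB <- dB - eta * Eeff * B
      dBP <- gg * Eeff * B[ipers] - hh * BP
      dB[ipers] <- dB[ipers] - gg * Eeff * B[ipers] + hh * BP
      dLY <- v_L * sum(B * rp)
    }
    r <- r + dt * dr
    B <- B + dt * dB
    P <- P + dt * dP
    Mp <- Mp + dt * (fluxp - lag)
    if (extd) {
      LY <- LY + dt * dLY
      BP <- BP + dt * dBP
      bneg <- BP < 0
      if (any(bneg)) { clips <- clips + sum(bneg); BP[bneg] <- 0 }
    }
    bufmat[, ptr] <- fluxp
    ptr <- if (ptr == L) 1L else ptr + 1L
    # Monte Carlo genotype creation, from the cohort that burst this step
    if (do_bim) {
      pb <- m * lag[g$bsel] * dtV
      if (unit_mode) {
        if (any(pb >= 1))
          stop("per-step BIM event probability reached 1 at t = ",
               format(t0 + s * dt),
               " h; reduce dt or use event_mode = \"poisson\"")
        cnt <- as.integer(stats::runif(length(pb)) < pb)
      } else cnt <- stats::rpois(length(pb), pb)
      for (w in which(cnt > 0L)) {
        B[g$bdest[w]] <- B[g$bdest[w]] + cnt[w] / V
        nev <- nev + 1L
        if (nev > nrow(ev)) ev <- rbind(ev, matrix(NA_real_, nrow(ev), 5L))
        ev[nev, ] <- c(t0 + s * dt, 1, g$bfrom[w], g$bfrom[w] + 1L, cnt[w])
      }
    }
    if (do_cem) {
      pc <- mu * lag[g$csel] * bm1 * dtV
      if (unit_mode) {
        if (any(pc >= 1))
          stop("per-step CEM event probability reached 1 at t = ",
               format(t0 + s * dt),
               " h; reduce dt or use event_mode = \"poisson\"")
        cnt <- as.integer(stats::runif(length(pc)) < pc)
      } else cnt <- stats::rpois(length(pc), pc)
      for (w in which(cnt > 0L)) {
        P[g$cdest[w]] <- P[g$cdest[w]] + cnt[w] / V
        P[g$cfrom[w] + 1L] <- max(P[g$cfrom[w] + 1L] - cnt[w] / V, 0)
        nev <- nev + 1L
        if (nev > nrow(ev)) ev <- rbind(ev, matrix(NA_real_, nrow(ev), 5L))
        ev[nev, ] <- c(t0 + s * dt, 2, g$cfrom[w], g$cfrom[w] + 1L, cnt[w])
      }
    }
    # negative-density protection
    if (r < 0) { clips <- clips + 1L; r <- 0 }
    neg <- B < 0
    if (any(neg)) { clips <- clips + sum(neg); B[neg] <- 0 }
    neg <- P < 0
    if (any(neg)) { clips <- clips + sum(neg); P[neg] <- 0 }
    neg <- Mp < 0
    if (any(neg)) { clips <- clips + sum(neg); Mp[neg] <- 0 }
    if (n_samp > 0L && s %% out_steps == 0L) {
      isamp <- isamp + 1L
      samp[isamp, ] <- if (extd) c(t0 + s * dt, r, B, P, Mp, LY, BP)
                       else c(t0 + s * dt, r, B, P, Mp)
    }
  }
  env$r <- r; env$B <- B; env$P <- P; env$Mp <- Mp
  env$LY <- LY; env$BP <- BP
  env$bufmat <- bufmat; env$ptr <- ptr
  env$t <- t0 + n_steps * dt
  env$clips <- clips
  env$ev <- ev; env$nev <- nev
  env$samples <- samp
  env
}

# Build the internal engine representation from a scenario-like bundle.
.engine_init <- function(init, params, ext, control) {
  g <- .engine_geometry(params, ext)
  if (length(init$B) != g$nb || length(init$P) != g$np)
    stop("initial state dimensions do not match the model parameters")
  buf <- delay_buffer(params$lam, control$dt, g$nb, g$np, M0 = init$M)
  Mp <- init$M[cbind(g$pih, g$pjp)]
  extd <- g$extended
  if (extd && !isTRUE(init$extended))
    stop("extended parameters given but the initial state is not extended ",
         "(construct it with community_state(..., extended = TRUE))")
  list(t = init$t, r = init$r, B = init$B, P = init$P, Mp = Mp,
       LY = if (extd) init$LY else 0,
       BP = if (extd) init$BP else numeric(0),
       bufmat = buf$mat, ptr = buf$ptr, geom = g, clips = 0L,
       ev = matrix(NA_real_, 64L, 5L), nev = 0L)
}

.engine_state <- function(env, params) {
  g <- env$geom
  M <- matrix(0, g$nb, g$np)
  M[cbind(g$pih, g$pjp)] <- env$Mp
  community_state(r = env$r, B = env$B, P = env$P, M = M, t = env$t,
                  extended = g$extended,
                  LY = if (g$extended) env$LY else 0,
                  BP = if (g$extended) env$BP else NULL)
}

#' Advance a simulation by single Euler/Monte-Carlo steps
#'
#' Low-level access to the hybrid stepper, mainly for inspection and testing:
#' each step (1) reads the lagged infection fluxes from the delay buffer,
#' (2) applies the deterministic right-hand side by explicit Euler,
#' (3) pushes the current infection fluxes into the buffer, (4) draws and
#' applies Monte Carlo BIM/CEM creation events, (5) clips negative densities
#' to zero, (6) logs events.  For whole runs use [run_scenario()].
#'
#' @param engine An engine created by [sim_engine()].
#' @param n_steps Number of steps to advance.
#' @return The updated engine; its `$state` field holds the current
#'   [community_state()].
#' @seealso [sim_engine()], [run_scenario()]
#' @export
sim_step <- function(engine, n_steps = 1L) {
  env <- .engine_run(engine$env, engine$params, engine$ext, engine$control,
                     as.integer(n_steps))
  engine$env <- env
  engine$state <- .engine_state(env, engine$params)
  engine
}

#' Create a stepping engine from model components
#'
#' @param init Initial [community_state()].
#' @param params [model_params()].
#' @param ext Optional [extended_params()].
#' @param control [sim_control()].
#' @return An engine object for [sim_step()].
#' @export
sim_engine <- function(init, params, ext = NULL, control = sim_control()) {
  if (!is.null(control$seed)) set.seed(control$seed)
  env <- .engine_init(init, params, ext, control)
  structure(list(env = env, params = params, ext = ext, control = control,
                 state = init),
            class = "sim_engine")
}

#' Apply a serial transfer (dilution into fresh medium)
#'
#' Divides every biological state variable (bacteria, phage, infected
#' cohorts, persisters, the LY compound, and the delay-buffer fluxes) by the
#' dilution factor and resets the resource to the fresh concentration
#' `schedule$R`.  With `stochastic_rounding` on, free populations (B, P, BP)
#' whose expected diluted count is below 10 individuals are resampled from a
#' binomial with retention probability `1/dilution`, so small populations can
#' go extinct at a transfer; infected cohorts and buffer entries are always
#' diluted deterministically.
#'
#' @param state A [community_state()].
#' @param schedule A [transfer_schedule()].
#' @param buffer Optional [delay_buffer()] to dilute alongside the state.
#' @param volume Culture volume (ml), defining the individual granularity for
#'   stochastic rounding.
#' @return A list with the transferred `state` and (possibly `NULL`)
#'   `buffer`.
#' @export
serial_transfer <- function(state, schedule, buffer = NULL, volume = 1) {
  d <- schedule$dilution
  thin <- function(x) {
    if (schedule$stochastic_rounding) {
      for (q in seq_along(x)) {
        if (x[q] * volume / d < 10) {
          n0 <- round(x[q] * volume)
          x[q] <- stats::rbinom(1L, n0, 1 / d) / volume
        } else x[q] <- x[q] / d
      }
      x
    } else x / d
  }
  state$B <- thin(state$B)
  state$P <- thin(state$P)
  state$M <- state$M / d
  if (isTRUE(state$extended)) {
    state$BP <- thin(state$BP)
    state$LY <- state$LY / d
  }
  state$r <- schedule$R
  if (!is.null(buffer)) buffer$mat <- buffer$mat / d
  list(state = state, buffer = buffer)
}

# Transfer applied to the internal engine representation.
.engine_transfer <- function(env, schedule, volume) {
  g <- env$geom
  st <- .engine_state(env, NULL)
  tr <- serial_transfer(st, schedule,
                        buffer = list(mat = env$bufmat), volume = volume)
  env$r <- tr$state$r
  env$B <- tr$state$B
  env$P <- tr$state$P
  env$Mp <- tr$state$M[cbind(g$pih, g$pjp)]
  if (g$extended) { env$LY <- tr$state$LY; env$BP <- tr$state$BP }
  env$bufmat <- tr$buffer$mat
  env
}
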