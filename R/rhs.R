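#' Monod growth-rate function
#'
#' Per-capita growth rate as a saturating function of the limiting resource:
#' `v * r / (r + k)`.  At `r = k` the rate is half-maximal (`v / 2`).
#'
#' @param r Resource concentration (ug/ml), non-negative.
#' @param v Maximum growth rate (per hour).
#' @param k Monod constant (ug/ml), positive.
#' @return Per-capita growth rate (per hour), bounded above by `v`.
#' @examples
#' monod_psi(350, v = 1.4, k = 1)  # close to v
#' monod_psi(1,   v = 1.4, k = 1)  # half-maximum
#' @export
monod_psi <- function(r, v, k) {
  if (any(r < 0)) stop("resource concentration 'r' must be non-negative")
  if (any(v < 0)) stop("'v' must be non-negative")
  if (any(k <= 0)) stop("'k' must be positive")
  v * r / (r + k)
}

#' Mass-action infection flux
#'
#' Rate at which phage of one order adsorb to (and, if replicative, infect)
#' bacteria of one order: `delta * Bi * Pj` (cells/ml/hr).  Bilinear in both
#' densities.
#'
#' @param Bi Host density (cells/ml).
#' @param Pj Phage density (phage/ml).
#' @param delta Adsorption rate constant (ml/cell/phage/hr).
#' @return Infection (adsorption) flux, cells/ml/hr.
#' @export
infection_flux <- function(Bi, Pj, delta) {
  if (any(Bi < 0) || any(Pj < 0) || any(delta < 0))
    stop("'Bi', 'Pj' and 'delta' must be non-negative")
  delta * Bi * Pj
}

#' Phage production from a bursting cohort
#'
#' Of the cells infected `lam` hours ago (flux `flux_at_lag`), a fraction
#' `1 - m` bursts (the rest become BIMs) and each burst releases `beta - 1`
#' free particles (the infecting particle was consumed at adsorption).
#'
#' @param flux_at_lag Lagged replicative infection flux (cells/ml/hr).
#' @param m Spacer-acquisition probability.
#' @param beta Burst size.
#' @return Phage production rate (phage/ml/hr): `(1 - m) * (beta - 1) * flux`.
#' @export
burst_release <- function(flux_at_lag, m, beta) {
  if (any(flux_at_lag < 0)) stop("'flux_at_lag' must be non-negative")
  if (any(m < 0) || any(m > 1)) stop("'m' must be in [0, 1]")
  (1 - m) * (beta - 1) * flux_at_lag
}

#' Deterministic right-hand side of the basic model
#'
#' Time-derivatives of resource, free bacteria, free phage and infected
#' cohorts, given the current state and the lagged infection fluxes (the
#' cohorts bursting now).  The Monte Carlo creation of BIMs and CEMs is *not*
#' part of these fluxes; it is layered on by the hybrid engine.
#'
#' The flux rules: bacteria grow at the Monod rate and are lost only to
#' replicative phage (phage order >= host order); phage are lost by
#' adsorption to *all* hosts (adsorption to an immune host destroys the
#' phage, not the host) and produced by bursting cohorts at
#' `(1 - m) (beta - 1)` per lagged infection; resource is consumed in
#' proportion to growth, `e` per new cell; each infected cohort gains the
#' current replicative infection flux and loses its lagged flux.
#'
#' @param state A [community_state()].
#' @param params A [model_params()].
#' @param lagged_flux Matrix (`n_orders x n_phage`) of infection fluxes from
#'   `lam` hours ago (cells/ml/hr); non-replicative entries must be zero.
#' @return List with elements `dr`, `dB`, `dP`, `dM` (same shapes as the
#'   state components).
#' @export
basic_rhs <- function(state, params, lagged_flux) {
  nb <- params$n_orders
  np <- params$n_phage
  if (length(state$B) != nb || length(state$P) != np)
    stop("state dimensions do not match 'params' order counts")
  lagged_flux <- as.matrix(lagged_flux)
  if (nrow(lagged_flux) != nb || ncol(lagged_flux) != np)
    stop("'lagged_flux' must be an n_orders x n_phage matrix")
  B <- state$B; P <- state$P; r <- state$r
  psi <- monod_psi(r, params$v, params$k)
  repmask <- outer(seq_len(nb) - 1L, seq_len(np) - 1L, "<=") * 1
  # replicative phage pressure on each host order: sum_{j >= i} P_j
  repP <- as.vector(repmask %*% P)
  flux <- params$delta * outer(B, P) * repmask
  dr <- -params$e * psi * sum(B)
  dB <- psi * B - params$delta * B * repP
  dP <- -params$delta * P * sum(B) +
    burst_release(colSums(lagged_flux), params$m, params$beta)
  dM <- flux - lagged_flux
  list(dr = dr, dB = dB, dP = dP, dM = dM)
}

#' Production rate of the lysis-released compound
#'
#' LY is produced in proportion to replicative phage-host encounters:
#' `v_L * sum over pairs (j >= i) of B_i * P_j` (ug/ml/hr).
#'
#' @param state A [community_state()] (extended or not).
#' @param v_L Production rate constant.
#' @return dLY/dt (ug/ml/hr).
#' @export
ly_production_rate <- function(state, v_L) {
  nb <- length(state$B)
  np <- length(state$P)
  repmask <- outer(seq_len(nb) - 1L, seq_len(np) - 1L, "<=") * 1
  v_L * sum(outer(state$B, state$P) * repmask)
}

#' Saturating LY effect fraction
#'
#' `min(LY / K_L, 1)`: the effect of the compound saturates once its
#' concentration exceeds `K_L`.
#'
#' @param LY Compound concentration (ug/ml).
#' @param K_L Concentration of maximal effect (ug/ml).
#' @return Effect fraction in \[0, 1\].
#' @export
ly_effect <- function(LY, K_L) {
  if (any(LY < 0)) stop("'LY' must be non-negative")
  if (any(K_L <= 0)) stop("'K_L' must be positive")
  pmin(LY / K_L, 1)
}

#' Deterministic right-hand side of the extended model
#'
#' [basic_rhs()] plus the lysis-released-compound terms.  With effect
#' fraction `E = ly_effect(LY, K_L)`: all dividing bacterial populations are
#' killed at per-capita rate `eta * E`; sensitive orders 0 and 1 enter a
#' non-dividing persister state at rate `g * E` and return at rate `h`;
#' LY accumulates at [ly_production_rate()] and has no decay (it is removed
#' only by dilution at transfers).  Persisters do not grow, do not take up
#' resource, are not adsorbed, and are not killed by LY.
#'
#' @inheritParams basic_rhs
#' @param ext An [extended_params()].
#' @return List with `dr`, `dB`, `dP`, `dM`, `dLY`, `dBP`.
#' @export
extended_rhs <- function(state, params, ext, lagged_flux) {
  base <- basic_rhs(state, params, lagged_flux)
  E <- ly_effect(state$LY, ext$K_L)
  npers <- min(params$n_orders, 2L)
  ip <- seq_len(npers)
  dB <- base$dB - ext$eta * E * state$B
  dBP <- ext$g * E * state$B[ip] - ext$h * state$BP
  dB[ip] <- dB[ip] - ext$g * E * state$B[ip] + ext$h * state$BP
  c(base[c("dr")], list(dB = dB, dP = base$dP, dM = base$dM,
                        dLY = ly_production_rate(state, ext$v_L),
                        dBP = dBP))
}
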