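#' Rate constants of the basic phage-bacteria model
#'
#' Bundles all rate constants of the basic model of lytic phage growing on
#' bacteria with CRISPR-cas adaptive immunity.  Bacteria and phage occur in
#' *orders*: a host of order i carries i spacers, a phage of order j carries j
#' protospacer (or PAM) mutations and can replicate on hosts of order <= j.
#' Phage adsorb to hosts of every order; adsorption to a host on which the
#' phage cannot replicate destroys the phage (intracellular cleavage) and
#' leaves the host alive.
#'
#' @param v Maximum per-capita growth rate (per hour).
#' @param k Monod constant: resource concentration at half-maximal growth
#'   (ug/ml).
#' @param e Conversion efficiency: resource used per new cell (ug per cell).
#' @param delta Adsorption rate constant (ml per cell per phage per hour).
#' @param beta Burst size, phage particles produced per infected cell
#'   (must exceed 1; the infecting particle is consumed, so a burst adds
#'   `beta - 1` free phage).
#' @param lam Latent period (hours): delay between adsorption and lysis.
#' @param m Probability that a replicative infection turns the host into a
#'   BIM of the next order instead of lysing it (dimensionless, in \[0, 1\]).
#' @param mu Probability, per phage particle produced, that the particle is a
#'   CEM of the next order (dimensionless, in \[0, 1\]).
#' @param n_orders Number of bacterial orders (>= 1).
#' @param n_phage Number of phage orders (>= 1); defaults to `n_orders`.
#'   Host and phage order counts are independent: the extended model of the
#'   source system has hosts of orders 0..2 but phage of orders 0..1 only,
#'   and a lysate on a wild-type host has hosts of order 0 with phage of
#'   orders 0..1.
#'
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params(v = 1.4, k = 1, e = 5e-7, delta = 8e-8,
#'                   beta = 80, lam = 0.4)
#' @export
model_params <- function(v, k, e, delta, beta, lam, m = 0, mu = 0,
                         n_orders = 1L, n_phage = n_orders) {
  stopifnot(is.numeric(v), is.numeric(k), is.numeric(e), is.numeric(delta),
            is.numeric(beta), is.numeric(lam), is.numeric(m), is.numeric(mu))
  if (v < 0) stop("'v' must be non-negative")
  if (k <= 0) stop("'k' must be positive")
  if (e < 0) stop("'e' must be non-negative")
  if (delta < 0) stop("'delta' must be non-negative")
  if (beta <= 1) stop("'beta' (burst size) must exceed 1")
  if (lam <= 0) stop("'lam' (latent period) must be positive")
  if (m < 0 || m > 1) stop("'m' must be a probability in [0, 1]")
  if (mu < 0 || mu > 1) stop("'mu' must be a probability in [0, 1]")
  n_orders <- as.integer(n_orders)
  n_phage <- as.integer(n_phage)
  if (n_orders < 1L) stop("'n_orders' must be >= 1")
  if (n_phage < 1L) stop("'n_phage' must be >= 1")
  structure(
    list(v = v, k = k, e = e, delta = delta, beta = beta, lam = lam,
         m = m, mu = mu, n_orders = n_orders, n_phage = n_phage),
    class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  v=%g /h  k=%g ug/ml  e=%g ug/cell  delta=%g ml/cell/phage/h\n",
              x$v, x$k, x$e, x$delta))
  cat(sprintf("  beta=%g  lam=%g h  m=%g  mu=%g\n", x$beta, x$lam, x$m, x$mu))
  cat(sprintf("  host orders: %d   phage orders: %d\n", x$n_orders, x$n_phage))
  invisible(x)
}

#' Parameters of the lysis-released compound (extended model)
#'
#' The extended model adds an agent of collective concentration LY (ug/ml),
#' released in proportion to replicative phage-host encounters, that kills
#' dividing cells and drives sensitive cells into a non-dividing persister
#' state.  Killing and persistence entry both saturate at LY = `K_L`.
#'
#' @param v_L Production rate constant for LY (ug.ml/cell/phage/hr: production
#'   is `v_L * sum of B_i * P_j` over replicative pairs).
#' @param K_L LY concentration of maximal effect (ug/ml); the effect fraction
#'   is `min(LY / K_L, 1)`.
#' @param eta Maximum per-capita kill rate of dividing cells (per hour).
#' @param g Persistence-entry rate constant (per hour at full LY effect).
#' @param h Persistence-exit rate (per hour).
#'
#' @return An object of class `extended_params`.
#' @examples
#' extended_params(v_L = 1e-6, K_L = 1e6, eta = 1.4, g = 0.01, h = 0.01)
#' @export
extended_params <- function(v_L = 0, K_L = 1e6, eta = 0, g = 0, h = 0) {
  if (v_L < 0 || eta < 0 || g < 0 || h < 0)
    stop("extended-model rates must be non-negative")
  if (K_L <= 0) stop("'K_L' must be positive")
  structure(list(v_L = v_L, K_L = K_L, eta = eta, g = g, h = h),
            class = "extended_params")
}

#' @export
print.extended_params <- function(x, ...) {
  cat(sprintf("<extended_params> v_L=%g  K_L=%g  eta=%g  g=%g  h=%g\n",
              x$v_L, x$K_L, x$eta, x$g, x$h))
  invisible(x)
}
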