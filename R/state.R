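#' Community state at a time point
#'
#' Snapshot of a batch culture: resource concentration, free bacteria and
#' phage per order, and infected ("fated") cohorts per replicative
#' (host order i, phage order j) pair with j >= i.  When `extended = TRUE`
#' the state also carries the lysis-released compound concentration `LY` and
#' persister densities `BP` (orders 0 and 1 only).
#'
#' @param r Resource concentration (ug/ml).
#' @param B Bacterial densities per order, cells/ml (length `n_orders`).
#' @param P Phage densities per order, phage/ml (length `n_phage`).
#' @param M Infected-cohort densities, an `n_orders x n_phage` matrix
#'   (cells/ml); entries with phage order < host order must be zero.
#'   Defaults to all-zero.
#' @param t Time (hours).
#' @param extended Carry the extended-model variables?
#' @param LY Lysis-released compound concentration (ug/ml).
#' @param BP Persister densities (cells/ml), one per persister-capable order
#'   (orders 0 and 1; length `min(length(B), 2)`).
#'
#' @return An object of class `community_state`.
#' @examples
#' community_state(r = 350, B = c(2e6, 0, 2e6), P = c(2e6, 0),
#'                 extended = TRUE)
#' @export
community_state <- function(r, B, P, M = NULL, t = 0,
                            extended = FALSE, LY = 0, BP = NULL) {
  nb <- length(B)
  np <- length(P)
  if (is.null(M)) M <- matrix(0, nb, np)
  M <- as.matrix(M)
  if (nrow(M) != nb || ncol(M) != np)
    stop("'M' must be a length(B) x length(P) matrix")
  if (r < 0) stop("resource concentration must be non-negative")
  if (any(B < 0) || any(P < 0) || any(M < 0))
    stop("densities must be non-negative")
  nonrep <- outer(seq_len(nb) - 1L, seq_len(np) - 1L, ">")
  if (any(M[nonrep] != 0))
    stop("infected cohorts exist only for replicative pairs (phage order >= host order)")
  if (extended) {
    npers <- min(nb, 2L)
    if (is.null(BP)) BP <- numeric(npers)
    if (length(BP) != npers)
      stop(sprintf("'BP' must have length %d", npers))
    if (LY < 0 || any(BP < 0))
      stop("'LY' and 'BP' must be non-negative")
  } else {
    if (LY != 0 || (!is.null(BP) && any(BP != 0)))
      stop("LY/BP given but 'extended' is FALSE")
    BP <- NULL
    LY <- NULL
  }
  structure(list(t = t, r = r, B = as.numeric(B), P = as.numeric(P), M = M,
                 LY = LY, BP = BP, extended = extended),
            class = "community_state")
}

#' @export
print.community_state <- function(x, ...) {
  cat(sprintf("<community_state> t=%g h  r=%.4g ug/ml\n", x$t, x$r))
  cat("  B:", format(x$B, digits = 4), "\n")
  cat("  P:", format(x$P, digits = 4), "\n")
  cat("  sum(M):", format(sum(x$M), digits = 4), "\n")
  if (isTRUE(x$extended))
    cat(sprintf("  LY=%.4g  BP: %s\n", x$LY,
                paste(format(x$BP, digits = 4), collapse = " ")))
  invisible(x)
}

#' Latent-period delay buffer
#'
#' Per replicative (host order, phage order) pair, a circular record of the
#' infection fluxes (cells/ml/hr) over the last `lam` hours.  The entry read
#' at each step is the flux of infections started exactly `lam` hours ago,
#' i.e. the cohort bursting now.  `lam` must be an integer multiple of the
#' step width so the delay bookkeeping is exact (no interpolation).
#'
#' @param lam Latent period (hours).
#' @param dt Step width (hours); `lam / dt` must be integral.
#' @param n_orders,n_phage Host and phage order counts.
#' @param M0 Optional initial infected-cohort matrix (cells/ml); spread as a
#'   uniform flux `M0 / lam` over the buffer so that
#'   `rowSums(buffer) * dt == M0` holds from the start.
#'
#' @return An object of class `delay_buffer`: a matrix with one row per
#'   replicative pair and `lam / dt` columns, plus a read/write pointer.
#' @export
delay_buffer <- function(lam, dt, n_orders, n_phage = n_orders, M0 = NULL) {
  L <- lam / dt
  if (abs(L - round(L)) > 1e-8 * max(1, L))
    stop(sprintf("latent period (%g h) must be an integer multiple of dt (%g h)",
                 lam, dt))
  L <- as.integer(round(L))
  if (L < 1L) stop("delay buffer needs at least one slot (lam >= dt)")
  pr <- replicative_pairs(n_orders, n_phage)
  mat <- matrix(0, nrow(pr), L)
  if (!is.null(M0)) {
    M0 <- as.matrix(M0)
    mat[] <- M0[cbind(pr$i + 1L, pr$j + 1L)] / lam
  }
  structure(list(mat = mat, ptr = 1L, dt = dt, lam = lam, pairs = pr,
                 n_orders = as.integer(n_orders), n_phage = as.integer(n_phage)),
            class = "delay_buffer")
}

#' Replicative (host order, phage order) pairs
#'
#' Enumerates the pairs on which phage replication (and hence an infected
#' cohort) exists: phage order j >= host order i.  Orders are 0-based, rows
#' are ordered by host then phage order; this ordering fixes the Monte Carlo
#' draw order and is part of the reproducibility contract.
#'
#' @param n_orders,n_phage Host and phage order counts.
#' @return A data.frame with 0-based columns `i` (host) and `j` (phage).
#' @export
replicative_pairs <- function(n_orders, n_phage = n_orders) {
  g <- expand.grid(j = seq_len(n_phage) - 1L, i = seq_len(n_orders) - 1L)
  g <- g[g$j >= g$i, c("i", "j")]
  rownames(g) <- NULL
  g
}

#' Current infected-cohort densities implied by a delay buffer
#'
#' @param buf A [delay_buffer()].
#' @return Matrix of M densities (cells/ml), `n_orders x n_phage`.
#' @export
buffer_cohorts <- function(buf) {
  pr <- buf$pairs
  M <- matrix(0, buf$n_orders, buf$n_phage)
  M[cbind(pr$i + 1L, pr$j + 1L)] <- rowSums(buf$mat) * buf$dt
  M
}
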