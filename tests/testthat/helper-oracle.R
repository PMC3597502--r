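# Independent reference integrator for the one-order basic model (m = mu = 0):
# a straight history-array delay integrator, coded without the package's
# circular buffer or matrix bookkeeping, used as the oracle for the engine's
# delay/Euler arithmetic.
ref_basic_sim <- function(v, k, e, delta, beta, lam, r0, B0, P0,
                          dt, t_end, sample_every) {
  nlag <- as.integer(round(lam / dt))
  n <- as.integer(round(t_end / dt))
  every <- as.integer(round(sample_every / dt))
  fluxh <- numeric(n)
  r <- r0; B <- B0; P <- P0; M <- 0
  ns <- n %/% every
  out <- matrix(NA_real_, ns + 1L, 5L,
                dimnames = list(NULL, c("time_h", "r", "B", "P", "M")))
  out[1L, ] <- c(0, r, B, P, M)
  row <- 1L
  for (s in seq_len(n)) {
    f <- delta * B * P
    lag <- if (s > nlag) fluxh[s - nlag] else 0
    psi <- v * r / (r + k)
    r2 <- r - dt * e * psi * B
    B2 <- B + dt * (psi * B - f)
    P2 <- P + dt * (-f + (beta - 1) * lag)
    M2 <- M + dt * (f - lag)
    fluxh[s] <- f
    r <- max(r2, 0); B <- max(B2, 0); P <- max(P2, 0); M <- max(M2, 0)
    if (s %% every == 0L) {
      row <- row + 1L
      out[row, ] <- c(s * dt, r, B, P, M)
    }
  }
  as.data.frame(out)
}

# Reference parameter set used throughout the tests.
ref_params1 <- function(...) {
  model_params(v = 1.4, k = 1, e = 5e-7, delta = 8e-8, beta = 80, lam = 0.4,
               n_orders = 1L, ...)
}

# Memoised expensive runs shared between test files.
.test_cache <- new.env(parent = emptyenv())
run_cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache))
    assign(key, force(expr), envir = .test_cache)
  get(key, envir = .test_cache)
}

# Trajectory columns only, stripped of scenario/event attributes, so that
# trajectories from different scenarios can be compared for equality.
bare_df <- function(ts) as.data.frame(as.list(ts))

# Row index of the sample closest to time h.
at_time <- function(ts, h) which.min(abs(ts$time_h - h))

sample_skewness <- function(x) {
  z <- (x - mean(x)) / stats::sd(x)
  mean(z^3)
}
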